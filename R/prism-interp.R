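# A bundled interpreter for the generated model-checker dialect.
#
# It parses exactly the command set that emit_model() produces (synchronous
# [PBN] commands, bool/bounded-int variables, formula definitions, a
# rewards block, and an Rmin reachability property), builds the product
# MDP over the reachable states, and hands it to the native
# min_reachability_reward() solver.  Generated code and native solver are
# thereby mutual oracles: probabilities are parsed from the same exact
# decimal literals, multiplied in the same module order, and successors
# are ordered canonically, so both routes produce identical numbers.

parse_prism <- function(model_text) {
  lines <- trimws(strsplit(model_text, "\n", fixed = TRUE)[[1]])
  lines <- lines[lines != "" & !startsWith(lines, "//")]
  if (lines[1] != "mdp;") stop("expected an mdp model", call. = FALSE)
  lines <- lines[-1]
  formulas <- list()
  modules <- list()
  rewards <- list(trans = list(), state = list())
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^formula ", ln)) {
      mm <- regmatches(ln, regexec("^formula ([A-Za-z_][A-Za-z0-9_]*) = (.*);$", ln))[[1]]
      if (length(mm) != 3) stop("bad formula line: ", ln, call. = FALSE)
      formulas[[mm[2]]] <- mm[3]
      i <- i + 1L
    } else if (grepl("^module ", ln)) {
      name <- sub("^module ", "", ln)
      vars <- list()
      cmds <- list()
      i <- i + 1L
      while (lines[i] != "endmodule") {
        l2 <- lines[i]
        if (grepl("^\\[PBN\\]", l2)) {
          mm <- regmatches(l2, regexec("^\\[PBN\\] (.*) -> (.*);$", l2))[[1]]
          if (length(mm) != 3) stop("bad command line: ", l2, call. = FALSE)
          cmds[[length(cmds) + 1L]] <- list(guard = prism_expr(mm[2]),
                                            branches = parse_branches(mm[3]))
        } else {
          mm <- regmatches(l2, regexec(
            "^([A-Za-z_][A-Za-z0-9_]*) : (bool|\\[(-?[0-9]+)\\.\\.(-?[0-9]+)\\]) init ([A-Za-z0-9]+);$", l2))[[1]]
          if (length(mm) == 0) stop("bad declaration line: ", l2, call. = FALSE)
          init <- switch(mm[6], "true" = 1L, "false" = 0L, as.integer(mm[6]))
          vars[[mm[2]]] <- list(init = init,
                                lo = if (mm[3] == "bool") 0L else as.integer(mm[4]),
                                hi = if (mm[3] == "bool") 1L else as.integer(mm[5]))
        }
        i <- i + 1L
      }
      modules[[name]] <- list(vars = vars, cmds = cmds)
      i <- i + 1L
    } else if (grepl("^rewards", ln)) {
      i <- i + 1L
      while (lines[i] != "endrewards") {
        l2 <- lines[i]
        if (grepl("^\\[PBN\\]", l2)) {
          mm <- regmatches(l2, regexec("^\\[PBN\\] (.*) : ([0-9.]+);$", l2))[[1]]
          rewards$trans[[length(rewards$trans) + 1L]] <-
            list(guard = prism_expr(mm[2]), reward = dec_to_num(dec_parse(mm[3])),
                 reward_str = mm[3])
        } else {
          mm <- regmatches(l2, regexec("^(.*) : ([0-9.]+);$", l2))[[1]]
          rewards$state[[length(rewards$state) + 1L]] <-
            list(guard = prism_expr(mm[2]), reward = dec_to_num(dec_parse(mm[3])),
                 reward_str = mm[3])
        }
        i <- i + 1L
      }
      i <- i + 1L
    } else {
      stop("unrecognized line: ", ln, call. = FALSE)
    }
  }
  list(formulas = formulas, modules = modules, rewards = rewards)
}

# translate a guard / arithmetic expression of the dialect into an R call
prism_expr <- function(txt) {
  s <- txt
  s <- gsub("\\btrue\\b", "1", s)
  s <- gsub("\\bfalse\\b", "0", s)
  # '=' -> '==' but keep <=, >=, !=
  s <- gsub("(?<![<>=!])=(?!=)", "==", s, perl = TRUE)
  str2lang(s)
}

parse_branches <- function(rhs) {
  parts <- strsplit(rhs, " + ", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    if (grepl(" : ", p, fixed = TRUE)) {
      at <- regexpr(" : ", p, fixed = TRUE)
      prob_lit <- trimws(substr(p, 1L, at - 1L))
      upd <- substr(p, at + 3L, nchar(p))
    } else {
      prob_lit <- "1"
      upd <- p
    }
    um <- gregexpr("\\(([A-Za-z_][A-Za-z0-9_]*)'=([^)]+)\\)", upd)[[1]]
    if (um[1] == -1) stop("bad update: ", upd, call. = FALSE)
    lens <- attr(um, "match.length")
    ups <- lapply(seq_along(um), function(k) {
      piece <- substr(upd, um[k], um[k] + lens[k] - 1L)
      mm <- regmatches(piece, regexec("^\\((\\w+)'=(.+)\\)$", piece))[[1]]
      list(var = mm[2], expr = prism_expr(mm[3]))
    })
    list(prob_str = prob_lit, prob_dec = dec_parse(prob_lit),
         prob = dec_to_num(dec_parse(prob_lit)), updates = ups)
  })
}

# canonical state ordering: t, x*, d*, s, p*, u*, ct* (matching the native
# augmented-MDP layer ordering)
prism_var_order <- function(var_names) {
  rank <- function(v) {
    if (v == "t") return(c(0, 0))
    if (grepl("^x[0-9]+$", v)) return(c(1, as.integer(sub("x", "", v))))
    if (grepl("^d[0-9]+$", v)) return(c(2, as.integer(sub("d", "", v))))
    if (v == "s") return(c(3, 0))
    if (grepl("^p[0-9]+$", v)) return(c(4, as.integer(sub("p", "", v))))
    if (v == "u") return(c(5, 0))
    if (grepl("^u[0-9]+$", v)) return(c(5, as.integer(sub("u", "", v))))
    if (grepl("^ct[0-9]+$", v)) return(c(6, as.integer(sub("ct", "", v))))
    c(7, 0)
  }
  rk <- t(vapply(var_names, rank, numeric(2)))
  var_names[order(rk[, 1], rk[, 2])]
}

#' Interpret generated model-checker code
#'
#' Parses a model/property pair produced by [emit_model()], constructs the
#' product MDP over the states reachable from the declared initial values,
#' and solves the minimum reachability reward with
#' [min_reachability_reward()].
#'
#' @param artifact A `pbn_prism` object, or a list with `model` and
#'   `property` strings.
#' @return A list with `value` (Rmin at the initial state), `mdp`,
#'   `solution` (the full solver output) and `n_states`.
#' @examples
#' art <- emit_model(example_problem(), forced_u0 = 0)
#' interpret_prism(art)$value
#' @export
interpret_prism <- function(artifact) {
  pp <- parse_prism(artifact$model)
  tm <- regmatches(artifact$property,
                   regexec("^Rmin=\\? \\[ F \\((.*)\\) \\]$", artifact$property))[[1]]
  if (length(tm) != 2) stop("unsupported property: ", artifact$property, call. = FALSE)
  target_pred <- prism_expr(tm[2])

  mods <- pp$modules
  var_decl <- unlist(lapply(mods, function(mo) mo$vars), recursive = FALSE)
  names(var_decl) <- unlist(lapply(mods, function(mo) names(mo$vars)))
  vn <- names(var_decl)
  vord <- prism_var_order(vn)
  init <- vapply(var_decl, function(v) v$init, integer(1))

  fnames <- names(pp$formulas)
  fexprs <- lapply(pp$formulas, prism_expr)

  env_of <- function(vals) {
    e <- list2env(as.list(vals), parent = baseenv())
    for (k in seq_along(fnames)) {
      assign(fnames[k], eval(fexprs[[k]], e), envir = e)
    }
    e
  }
  key_of <- function(vals) paste(vals[vord], collapse = ",")

  # breadth-first discovery
  branch_cache <- new.env(parent = emptyenv())
  idmap <- new.env(parent = emptyenv())
  states <- list(init)
  idmap[[key_of(init)]] <- 1L
  trans <- list()
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (sid in frontier) {
      vals <- states[[sid]]
      e <- env_of(vals)
      enabled <- lapply(mods, function(mo) {
        which(vapply(mo$cmds, function(cm) as.logical(eval(cm$guard, e)), logical(1)))
      })
      if (any(vapply(enabled, length, integer(1)) == 0L)) {
        stop("deadlocked module in interpreted model", call. = FALSE)
      }
      combos <- expand_choices(enabled)
      acts <- list()
      for (co in combos) {
        bkey <- paste(co, collapse = "_")
        branches <- branch_cache[[bkey]]
        if (is.null(branches)) {
          branches <- list(list(dec = dec_one(), upd = list()))
          for (mi in seq_along(mods)) {
            cm <- mods[[mi]]$cmds[[co[mi]]]
            branches <- unlist(lapply(branches, function(br) {
              lapply(cm$branches, function(b2) {
                list(dec = dec_mul(br$dec, b2$prob_dec),
                     upd = c(br$upd, b2$updates))
              })
            }), recursive = FALSE)
          }
          branch_cache[[bkey]] <- branches
        }
        dest <- integer(0)
        prob <- numeric(0)
        for (br in branches) {
          nv <- vals
          for (up in br$upd) nv[[up$var]] <- as.integer(eval(up$expr, e))
          bad <- nv < vapply(var_decl, function(v) v$lo, integer(1)) |
                 nv > vapply(var_decl, function(v) v$hi, integer(1))
          if (any(bad)) stop("variable out of range in interpreted model", call. = FALSE)
          kk <- key_of(nv)
          did <- idmap[[kk]]
          if (is.null(did)) {
            states[[length(states) + 1L]] <- nv
            did <- length(states)
            idmap[[kk]] <- did
            nxt <- c(nxt, did)
          }
          p <- dec_to_num(br$dec)
          at <- match(did, dest)
          if (is.na(at)) {
            dest <- c(dest, did)
            prob <- c(prob, p)
          } else {
            prob[at] <- prob[at] + p
          }
        }
        tr <- sum(vapply(pp$rewards$trans, function(rw) {
          if (as.logical(eval(rw$guard, e))) rw$reward else 0
        }, numeric(1)))
        acts[[length(acts) + 1L]] <- list(dest = dest, prob = prob, reward = tr)
      }
      trans[[sid]] <- acts
    }
    frontier <- nxt
  }

  # canonical renumbering
  keys <- vapply(states, key_of, character(1))
  keymat <- do.call(rbind, lapply(states, function(v) v[vord]))
  ord <- do.call(order, as.data.frame(keymat))
  newid <- integer(length(states)); newid[ord] <- seq_along(states)
  states2 <- states[ord]
  actions <- vector("list", length(states))
  srew <- numeric(length(states))
  targ <- logical(length(states))
  for (sid in seq_along(states)) {
    nid <- newid[sid]
    actions[[nid]] <- lapply(trans[[sid]], function(a) {
      dd <- newid[a$dest]
      oo <- order(dd)
      list(label = "", dest = dd[oo], prob = a$prob[oo], reward = a$reward)
    })
    e <- env_of(states[[sid]])
    srew[nid] <- sum(vapply(pp$rewards$state, function(rw) {
      if (as.logical(eval(rw$guard, e))) rw$reward else 0
    }, numeric(1)))
    targ[nid] <- as.logical(eval(target_pred, e))
  }
  mdp <- new_mdp(actions, state_reward = srew, target = which(targ),
                 init = newid[1L])
  sol <- min_reachability_reward(mdp, tol = 0, max_iter = length(states2) + 2L)
  list(value = sol$value[newid[1L]], mdp = mdp, solution = sol,
       n_states = length(states2))
}

# cartesian product of enabled-command choices, first module slowest
expand_choices <- function(enabled) {
  combos <- list(integer(0))
  for (ch in enabled) {
    combos <- unlist(lapply(combos, function(co) {
      lapply(ch, function(c1) c(co, c1))
    }), recursive = FALSE)
  }
  combos
}
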