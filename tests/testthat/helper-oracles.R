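# Independent oracles and fixture generators used across the suite.

# ---- Boolean expression oracle -------------------------------------------
# Evaluates an expression string through R's own logical operators after
# textual substitution -- a code path fully independent of the package's
# AST evaluator.
bool_oracle <- function(text, x, u, genes, controls) {
  vals <- c(stats::setNames(as.list(as.logical(x)), genes),
            stats::setNames(as.list(as.logical(u)), controls))
  e <- str2lang(text)
  as.integer(eval(e, vals))
}

# all 0/1 assignments as rows
assignment_grid <- function(k) {
  if (k == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  as.matrix(rev(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE])
}

# numeric evaluation of an arithmetized expression string
arith_oracle <- function(text, x, u, genes, controls) {
  vals <- c(stats::setNames(as.list(as.numeric(x)), genes),
            stats::setNames(as.list(as.numeric(u)), controls))
  eval(str2lang(text), vals)
}

# ---- monolithic kernel oracle --------------------------------------------
# Rebuilds the one-step distribution of the delayed semantics by direct
# enumeration of all (switch', perturbation', function-choice) outcomes,
# using plain doubles and none of the package's kernel code.
kernel_oracle_delayed <- function(problem_net, state, u_bits) {
  n <- length(problem_net$genes)
  l <- vapply(problem_net$nodes, function(nd) length(nd$exprs), integer(1))
  q <- problem_net$q; p <- problem_net$p
  st <- state
  out <- new.env(parent = emptyenv())
  dcombos <- if (st$s == 1) {
    g <- do.call(expand.grid, lapply(l, seq_len))
    lapply(seq_len(nrow(g)), function(r) as.integer(g[r, ]))
  } else list(st$d)
  for (dn in dcombos) {
    wd <- if (st$s == 1) {
      prod(vapply(seq_len(n), function(i) problem_net$nodes[[i]]$probs[dn[i]], numeric(1)))
    } else 1
    xn <- vapply(seq_len(n), function(i) {
      if (st$per[i] == 1) 1L - st$x[i]
      else eval_expr(problem_net$nodes[[i]]$exprs[[dn[i]]], st$x, u_bits)
    }, integer(1))
    for (sn in 0:1) for (pc in 0:(2^n - 1)) {
      pn <- as.integer((pc %/% 2^((n - 1):0)) %% 2)
      w <- wd * ifelse(sn == 1, q, 1 - q) *
        prod(ifelse(pn == 1, p, 1 - p))
      key <- paste(c(xn, dn, sn, pn), collapse = "")
      out[[key]] <- (out[[key]] %||% 0) + w
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exhaustive-adversary oracle for generic MDPs ------------------------
# Every deterministic memoryless adversary, each evaluated by solving the
# linear backward system on its induced chain.
adversary_enum_value <- function(mdp) {
  ns <- mdp$n_states
  is_t <- rep(FALSE, ns); is_t[mdp$target] <- TRUE
  counts <- vapply(mdp$actions, length, integer(1))
  free <- which(!is_t & counts > 1)
  choice <- rep(1L, ns)
  best <- rep(Inf, ns)
  combos <- if (length(free)) {
    as.matrix(expand.grid(lapply(counts[free], seq_len)))
  } else matrix(1L, nrow = 1, ncol = 0)
  for (r in seq_len(nrow(combos))) {
    ch <- choice
    ch[free] <- as.integer(combos[r, ])
    P <- matrix(0, ns, ns)
    rvec <- numeric(ns)
    for (s in which(!is_t)) {
      a <- mdp$actions[[s]][[ch[s]]]
      P[s, a$dest] <- P[s, a$dest] + a$prob
      rvec[s] <- mdp$state_reward[s] + a$reward
    }
    # per state: the chain from s reaches the target almost surely iff no
    # state reachable from s lacks a positive-probability path to the
    # target (finite-chain graph argument)
    can <- is_t
    repeat {
      new <- !can & (P[, can, drop = FALSE] %*% rep(1, sum(can)) > 0)
      if (!any(new)) break
      can <- can | as.vector(new)
    }
    hits_bad <- !can
    repeat {
      new <- !hits_bad & (P[, hits_bad, drop = FALSE] %*% rep(1, sum(hits_bad)) > 0)
      if (!any(new)) break
      hits_bad <- hits_bad | as.vector(new)
    }
    v <- rep(Inf, ns)
    v[is_t] <- 0
    good <- which(!is_t & !hits_bad)
    if (length(good)) {
      v[good] <- solve(diag(length(good)) - P[good, good, drop = FALSE], rvec[good])
    }
    best <- pmin(best, v)
  }
  best[is_t] <- 0
  best
}

# ---- exhaustive-policy oracle on the time-augmented MDP ------------------
# Enumerates every deterministic assignment of actions to the decision
# states (where the choice can influence the cost) and evaluates each by
# forward distribution propagation; returns the minimum over assignments
# and over the initial conditions.  Arithmetic is plain double: with
# dyadic model probabilities and integer costs every operation is exact.
policy_enum_min <- function(mdp, exact = FALSE) {
  info <- attr(mdp, "info")
  K <- info$K
  st <- mdp$states
  is_t <- rep(FALSE, mdp$n_states); is_t[mdp$target] <- TRUE
  horizon_cut <- if (info$timing == "input") K - 2L else K - 1L
  dec_states <- which(!is_t & st$t <= horizon_cut &
                        vapply(mdp$actions, length, integer(1)) > 1)
  combos <- if (length(dec_states)) {
    as.matrix(expand.grid(lapply(vapply(mdp$actions[dec_states], length, integer(1)),
                                 seq_len)))
  } else matrix(1L, nrow = 1, ncol = 0)
  eval_assignment <- function(ch_full, init) {
    if (exact) {
      dist <- stats::setNames(list(pbnctrl:::dec_one()), init)
      total <- pbnctrl:::dec_zero()
      for (sweep in 0:(K + 1)) {
        nd <- list()
        for (kk in names(dist)) {
          s <- as.integer(kk)
          w <- dist[[kk]]
          if (is_t[s]) { nd[[kk]] <- w; next }
          total <- pbnctrl:::dec_add(total,
            pbnctrl:::dec_mul(w, pbnctrl:::dec_parse(attr(mdp, "info")$rho_str[s])))
          a <- mdp$actions[[s]][[ch_full[s]]]
          total <- pbnctrl:::dec_add(total,
            pbnctrl:::dec_mul(w, pbnctrl:::dec_parse(a$reward_str)))
          for (j in seq_along(a$dest)) {
            k2 <- as.character(a$dest[j])
            pw <- pbnctrl:::dec_mul(w, a$dec[[j]])
            nd[[k2]] <- if (is.null(nd[[k2]])) pw else pbnctrl:::dec_add(nd[[k2]], pw)
          }
        }
        dist <- nd
      }
      total
    } else {
      dist <- numeric(mdp$n_states)
      dist[init] <- 1
      total <- 0
      for (sweep in 0:(K + 1)) {
        nd <- numeric(mdp$n_states)
        for (s in which(dist > 0)) {
          w <- dist[s]
          if (is_t[s]) { nd[s] <- nd[s] + w; next }
          a <- mdp$actions[[s]][[ch_full[s]]]
          total <- total + w * (mdp$state_reward[s] + a$reward)
          nd[a$dest] <- nd[a$dest] + w * a$prob
        }
        dist <- nd
      }
      total
    }
  }
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    ch_full <- rep(1L, mdp$n_states)
    ch_full[dec_states] <- as.integer(combos[r, ])
    for (init in mdp$init) {
      v <- eval_assignment(ch_full, init)
      if (exact) {
        if (is.null(best) || pbnctrl:::dec_cmp(v, best) < 0) best <- v
      } else {
        if (is.null(best) || v < best) best <- v
      }
    }
  }
  best
}

# ---- random instance generators ------------------------------------------
# Dyadic instances: all probabilities in {k/8} and {1/4, 1/2}, integer
# costs, so double arithmetic is exact end to end.
rand_problem_dyadic <- function(seed, n = 2, K = 2, l = 2, p_zero = FALSE) {
  withr::with_seed(seed, {
    q <- sample(c("0.25", "0.5"), 1)
    p <- if (p_zero) "0" else sample(c("0.25", "0.5"), 1)
    net <- random_network(n = n, m = 1, max_indegree = 2, l = l,
                          q = q, p = p, prob_denom = 8)
    xs <- vapply(0:(2^n - 1), function(c) {
      paste(pbnctrl:::code_to_bits(c, n), collapse = "")
    }, character(1))
    costs <- cost_spec(
      control = data.frame(u = "1", cost = sample(1:3, 1)),
      terminal = data.frame(x = xs, cost = sample(0:6, 2^n, replace = TRUE)),
      horizon = K
    )
    control_problem(net, costs,
                    x0 = sample(0:1, n, replace = TRUE),
                    d0 = vapply(rep(l, n), function(li) sample(li, 1), integer(1)))
  })
}

rand_problem_decimal <- function(seed, n = 2, K = 3, l = 2, q = "0.3", p = "0.1") {
  withr::with_seed(seed, {
    net <- random_network(n = n, m = 1, max_indegree = 2, l = l,
                          q = q, p = p, prob_denom = 10)
    xs <- vapply(0:(2^n - 1), function(c) {
      paste(pbnctrl:::code_to_bits(c, n), collapse = "")
    }, character(1))
    costs <- cost_spec(
      control = data.frame(u = "1", cost = 1),
      terminal = data.frame(x = xs, cost = sample(0:6, 2^n, replace = TRUE)),
      horizon = K
    )
    control_problem(net, costs, x0 = sample(0:1, n, replace = TRUE))
  })
}
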