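# Backward induction on the time-augmented MDP, policy extraction and
# policy evaluation.

#' Solve the finite-horizon optimal control problem
#'
#' Minimizes the expected cumulated control cost plus terminal cost over
#' the horizon by a single backward sweep over the time-augmented MDP
#' (equivalently, the minimum reachability reward to the `t = K+1` layer).
#'
#' @inheritParams build_augmented_mdp
#' @param exact If `TRUE`, the sweep runs in exact fixed-point decimal
#'   arithmetic (all model quantities are terminating decimals); the value
#'   is then also reported as an exact decimal string.  Intended for small
#'   instances.
#' @return A `pbn_solution` with elements `value` (the optimal expected
#'   cost from the initial condition), `policy` (tibble of optimal
#'   decisions), `value_table` (tibble of state values), `per_init`
#'   (input timing: value per initial control choice), `residual` (maximal
#'   Bellman residual over reachable states) and the solved `mdp`.
#'   [tidy()] returns the policy, [glance()] a one-row summary, and
#'   [autoplot()] draws the policy.
#' @examples
#' sol <- solve_finite_horizon(example_problem())
#' glance(sol)
#' @export
solve_finite_horizon <- function(problem, constraints = NULL,
                                 timing = c("input", "direct"),
                                 semantics = c("delayed", "immediate"),
                                 exact = FALSE) {
  timing <- match.arg(timing)
  semantics <- match.arg(semantics)
  mdp <- build_augmented_mdp(problem, constraints, timing, semantics)
  solution_from_mdp(mdp, exact)
}

#' Solve with the first control fixed
#'
#' The value of the control problem when the control in effect at step 0 is
#' fixed to `u0` and chosen optimally thereafter.  The minimum over all
#' `u0` equals [solve_finite_horizon()].
#'
#' @inheritParams solve_finite_horizon
#' @param u0 Control vector for step 0 (binary string or 0/1 vector).
#' @return A `pbn_solution` (see [solve_finite_horizon()]).
#' @examples
#' solve_with_forced_first_action(example_problem(), u0 = 1)$value
#' @export
solve_with_forced_first_action <- function(problem, u0, constraints = NULL,
                                           timing = c("input", "direct"),
                                           semantics = c("delayed", "immediate"),
                                           exact = FALSE) {
  timing <- match.arg(timing)
  semantics <- match.arg(semantics)
  mdp <- build_augmented_mdp(problem, constraints, timing, semantics,
                             forced_u0 = u0)
  solution_from_mdp(mdp, exact)
}

solution_from_mdp <- function(mdp, exact = FALSE) {
  info <- attr(mdp, "info")
  ns <- mdp$n_states
  is_t <- rep(FALSE, ns); is_t[mdp$target] <- TRUE
  v <- numeric(ns)
  vdec <- if (exact) rep(list(dec_zero()), ns) else NULL
  choice <- rep(NA_integer_, ns)
  # ids are layer-major, so one descending sweep is a full backward pass
  for (s in rev(seq_len(ns))) {
    if (is_t[s]) next
    acts <- mdp$actions[[s]]
    if (exact) {
      best <- NULL; best_k <- NA_integer_
      for (k in seq_along(acts)) {
        a <- acts[[k]]
        q <- dec_add(dec_parse(a$reward_str),
                     dec_sum(lapply(seq_along(a$dest), function(j) {
                       dec_mul(a$dec[[j]], vdec[[a$dest[j]]])
                     })))
        if (is.null(best) || dec_cmp(q, best) < 0) { best <- q; best_k <- k }
      }
      vdec[[s]] <- dec_add(dec_parse(info$rho_str[s]), best)
      v[s] <- dec_to_num(vdec[[s]])
      choice[s] <- best_k
    } else {
      qs <- vapply(acts, function(a) a$reward + sum(a$prob * v[a$dest]), numeric(1))
      choice[s] <- which.min(qs)
      v[s] <- mdp$state_reward[s] + qs[choice[s]]
    }
  }
  # optimal initial condition (input timing: minimize over u0; ties toward
  # the smaller control code, which comes first in id order)
  init <- mdp$init
  if (exact) {
    best <- init[1]
    for (s in init[-1]) if (dec_cmp(vdec[[s]], vdec[[best]]) < 0) best <- s
    i0 <- best
  } else {
    i0 <- init[which.min(v[init])]
  }
  st <- mdp$states
  per_init <- if (info$timing == "input" && is.null(info$forced_u0)) {
    tibble::tibble(u0 = st$u[init], value = v[init],
                   value_exact = if (exact) vapply(vdec[init], dec_format, character(1)) else NA_character_)
  } else NULL
  policy <- st[!is_t, , drop = FALSE]
  policy$action <- vapply(which(!is_t), function(s) {
    mdp$actions[[s]][[choice[s]]]$label
  }, character(1))
  policy$value <- v[!is_t]
  attr(policy, "timing") <- info$timing
  attr(policy, "semantics") <- info$semantics
  attr(policy, "init_id") <- i0
  if (info$timing == "input") {
    attr(policy, "u0") <- bits_to_code(string_to_bits_or_empty(st$u[i0]))
  }
  class(policy) <- c("pbn_policy", class(policy))
  vt <- st
  vt$value <- v
  if (exact) vt$value_exact <- vapply(vdec, dec_format, character(1))
  res <- bellman_residual(mdp, v)
  structure(list(
    value = v[i0],
    value_exact = if (exact) dec_format(vdec[[i0]]) else NULL,
    policy = policy, value_table = tibble::as_tibble(vt),
    per_init = per_init, mdp = mdp, choice = choice, init_id = i0,
    residual = res, timing = info$timing, semantics = info$semantics,
    exact = exact, constraints = info$constraints,
    forced_u0 = info$forced_u0, problem = info$problem
  ), class = "pbn_solution")
}

# max Bellman residual of a value vector over non-target states
bellman_residual <- function(mdp, v) {
  is_t <- rep(FALSE, mdp$n_states); is_t[mdp$target] <- TRUE
  res <- 0
  for (s in which(!is_t)) {
    qs <- vapply(mdp$actions[[s]], function(a) a$reward + sum(a$prob * v[a$dest]),
                 numeric(1))
    res <- max(res, abs(v[s] - (mdp$state_reward[s] + min(qs))))
  }
  res
}

#' @export
print.pbn_solution <- function(x, ...) {
  cat(sprintf("<pbn_solution> optimal expected cost %s over K = %d (%s timing, %s semantics)\n",
              format(x$value, digits = 10), x$problem$costs$horizon, x$timing, x$semantics))
  if (!is.null(x$value_exact)) cat("  exact value:", x$value_exact, "\n")
  if (!is.null(x$per_init)) {
    for (i in seq_len(nrow(x$per_init))) {
      cat(sprintf("  initial control %s : %s\n", x$per_init$u0[i],
                  format(x$per_init$value[i], digits = 10)))
    }
  }
  cat(sprintf("  augmented states: %d, Bellman residual: %.2e\n",
              x$mdp$n_states, x$residual))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.pbn_solution <- function(x, ...) {
  p <- x$policy
  class(p) <- setdiff(class(p), "pbn_policy")
  tibble::as_tibble(p)
}

#' @exportS3Method generics::glance
glance.pbn_solution <- function(x, ...) {
  tibble::tibble(
    value = x$value,
    horizon = x$problem$costs$horizon,
    n_states = x$mdp$n_states,
    timing = x$timing,
    semantics = x$semantics,
    exact = x$exact,
    residual = x$residual
  )
}

#' Per-step policy listing with decimal state numbers
#'
#' Lists, for each control step, the control in effect in every state
#' reachable under optimal play, with states numbered by the decimal
#' equivalent of their gene-state binary encoding (MSB = x1).  Because the
#' optimal decision may legitimately depend on the context, switch and
#' perturbation components, the listing also projects onto `(t, x)` and
#' flags projection conflicts: gene states whose decision differs between
#' contexts.
#'
#' @param solution A `pbn_solution`.
#' @return A tibble with columns `t`, `state_decimal`, `state_binary`,
#'   `d`, `s`, `per`, `control` and `conflict`; the number of conflicting
#'   `(t, x)` groups is in attribute `n_conflicts`.
#' @export
extract_policy_table <- function(solution) {
  mdp <- solution$mdp
  info <- attr(mdp, "info")
  K <- info$K
  st <- mdp$states
  # forward closure under the chosen decisions
  reach <- rep(FALSE, mdp$n_states)
  cur <- solution$init_id
  reach[cur] <- TRUE
  frontier <- cur
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in frontier) {
      if (is.na(solution$choice[s])) next
      a <- mdp$actions[[s]][[solution$choice[s]]]
      new <- a$dest[!reach[a$dest]]
      reach[new] <- TRUE
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  keep <- reach & st$t <= K - 1L
  rows <- st[keep, , drop = FALSE]
  ids <- rows$id
  control <- if (info$timing == "input") {
    rows$u
  } else {
    vapply(ids, function(s) mdp$actions[[s]][[solution$choice[s]]]$label, character(1))
  }
  out <- tibble::tibble(
    t = rows$t,
    state_decimal = rows$x_decimal,
    state_binary = rows$x,
    d = rows$d, s = rows$s, per = rows$per,
    control = control
  )
  out <- dplyr::arrange(out, .data$t, .data$state_decimal, .data$d, .data$s, .data$per)
  conf <- out |>
    dplyr::group_by(.data$t, .data$state_decimal) |>
    dplyr::summarise(conflict = dplyr::n_distinct(.data$control) > 1L, .groups = "drop")
  out <- dplyr::left_join(out, conf, by = c("t", "state_decimal"))
  attr(out, "n_conflicts") <- sum(conf$conflict)
  out
}

#' Expected cost of a fixed policy
#'
#' Exact expectation of the cumulated control plus terminal cost under a
#' given policy, by forward distribution propagation.
#'
#' @param problem A [control_problem()].
#' @param policy Either the `policy` tibble of a `pbn_solution` (its
#'   timing is respected), or a function `function(t, state)` returning a
#'   control vector, where `state` is a list with `x`, `d`, `s`, `per`
#'   (evaluated under direct timing: the control is applied in the same
#'   step).
#' @param semantics Kernel semantics; ignored when `policy` carries its
#'   own.
#' @param exact Propagate in exact decimal arithmetic and return the value
#'   as its exact string in attribute `"exact"`.
#' @return The expected cost (numeric scalar).
#' @examples
#' never <- function(t, state) 0
#' evaluate_policy(example_problem(), never)
#' @export
evaluate_policy <- function(problem, policy,
                            semantics = c("delayed", "immediate"),
                            exact = FALSE) {
  semantics <- match.arg(semantics)
  net <- problem$network
  K <- problem$costs$horizon
  m <- n_controls(net)
  cm <- cost_matrices(net, problem$costs)
  if (inherits(policy, "pbn_policy") || (is.data.frame(policy) && "action" %in% names(policy))) {
    timing <- attr(policy, "timing") %||% "direct"
    semantics <- attr(policy, "semantics") %||% semantics
    lookup <- policy_lookup(policy)
  } else if (is.function(policy)) {
    timing <- "direct"
    fn <- policy
    lookup <- function(t, base_idx, u_code, st) {
      bits_to_code(as_control(net, fn(t, st)))
    }
  } else {
    stop("policy must be a solution policy tibble or a function(t, state)", call. = FALSE)
  }
  ctx <- kernel_context(net, semantics)
  base0 <- encode_state(net, problem$x0, problem$d0, problem$s0, problem$per0)

  num <- function(x) if (exact) as_dec(x) else x
  add <- if (exact) dec_add else `+`
  mul <- if (exact) dec_mul else `*`
  total <- num(0)

  if (timing == "input") {
    u0 <- attr(policy, "u0") %||% lookup(0L, base0, NA_integer_, decode_state(net, base0))
    dist <- list(); dist[[paste(base0, u0)]] <- num(1)
    for (t in 0:(K - 1)) {
      if (K == 0L) break
      nd <- list()
      for (kk in names(dist)) {
        parts <- as.integer(strsplit(kk, " ")[[1]])
        base <- parts[1]; uc <- parts[2]
        w <- dist[[kk]]
        st <- decode_state(net, base)
        xr <- bits_to_code(st$x) + 1L
        total <- add(total, mul(w, num(if (exact) cm$g_str[xr, uc + 1L] else cm$g[xr, uc + 1L])))
        a <- lookup(t, base, uc, st)
        succ <- kernel_succ(ctx, base, uc)
        for (j in seq_along(succ$idx)) {
          k2 <- paste(succ$idx[j], a)
          pw <- mul(w, if (exact) succ$dec[[j]] else succ$prob[j])
          nd[[k2]] <- if (is.null(nd[[k2]])) pw else add(nd[[k2]], pw)
        }
      }
      dist <- nd
    }
    for (kk in names(dist)) {
      parts <- as.integer(strsplit(kk, " ")[[1]])
      st <- decode_state(net, parts[1])
      xr <- bits_to_code(st$x) + 1L
      total <- add(total, mul(dist[[kk]], num(if (exact) cm$gK_str[xr] else cm$gK[xr])))
    }
  } else {
    dist <- list(); dist[[as.character(base0)]] <- num(1)
    for (t in 0:(K - 1)) {
      if (K == 0L) break
      nd <- list()
      for (kk in names(dist)) {
        base <- as.integer(kk)
        w <- dist[[kk]]
        st <- decode_state(net, base)
        uc <- lookup(t, base, NA_integer_, st)
        xr <- bits_to_code(st$x) + 1L
        total <- add(total, mul(w, num(if (exact) cm$g_str[xr, uc + 1L] else cm$g[xr, uc + 1L])))
        succ <- kernel_succ(ctx, base, uc)
        for (j in seq_along(succ$idx)) {
          k2 <- as.character(succ$idx[j])
          pw <- mul(w, if (exact) succ$dec[[j]] else succ$prob[j])
          nd[[k2]] <- if (is.null(nd[[k2]])) pw else add(nd[[k2]], pw)
        }
      }
      dist <- nd
    }
    for (kk in names(dist)) {
      st <- decode_state(net, as.integer(kk))
      xr <- bits_to_code(st$x) + 1L
      total <- add(total, mul(dist[[kk]], num(if (exact) cm$gK_str[xr] else cm$gK[xr])))
    }
  }
  if (exact) {
    out <- dec_to_num(total)
    attr(out, "exact") <- dec_format(total)
    out
  } else {
    total
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lookup closure over a solution policy tibble
policy_lookup <- function(policy) {
  timing <- attr(policy, "timing") %||% "direct"
  if ("ct" %in% names(policy) && dplyr::n_distinct(policy$ct) > 1L) {
    stop("policies of hard-constrained solutions depend on the intervention counters; ",
         "use the solution value directly", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(policy))) {
    key <- if (timing == "input") {
      paste(policy$t[i], policy$x[i], policy$d[i], policy$s[i], policy$per[i], policy$u[i])
    } else {
      paste(policy$t[i], policy$x[i], policy$d[i], policy$s[i], policy$per[i])
    }
    env[[key]] <- bits_to_code(string_to_bits_or_empty(policy$action[i]))
  }
  function(t, base_idx, u_code, st) {
    key <- if (timing == "input") {
      paste(t, bits_to_string(st$x), paste(st$d, collapse = ","), st$s,
            bits_to_string(st$per), bits_to_string(code_to_bits(u_code, nchar(policy$u[1]))))
    } else {
      paste(t, bits_to_string(st$x), paste(st$d, collapse = ","), st$s,
            bits_to_string(st$per))
    }
    v <- env[[key]]
    if (is.null(v)) {
      stop(sprintf("policy gap: no decision for t = %d, state x=%s d=%s s=%d per=%s",
                   t, bits_to_string(st$x), paste(st$d, collapse = ","), st$s,
                   bits_to_string(st$per)), call. = FALSE)
    }
    v
  }
}

string_to_bits_or_empty <- function(s) {
  if (is.na(s) || s == "") integer() else string_to_bits(s)
}
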