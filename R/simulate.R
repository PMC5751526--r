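# Monte-Carlo estimation of the expected cost of a policy: the stochastic
# cross-check of the backward-induction value.

#' Simulate a policy
#'
#' Draws trajectories from the initial condition under a policy, accruing
#' the control cost at steps `0..K-1` and the terminal cost at step `K`.
#' Trajectories are propagated in bulk (grouped by state), so large
#' trajectory counts are cheap.
#'
#' @inheritParams evaluate_policy
#' @param n_traj Number of trajectories.
#' @param seed Integer seed; the draw is reproducible and the caller's RNG
#'   state is untouched.
#' @return A `pbn_simulation` with elements `samples` (realized costs),
#'   `mean`, `se` (standard error), `n_traj` and `seed`.  [glance()]
#'   returns the summary as a one-row tibble.
#' @examples
#' sol <- solve_finite_horizon(example_problem())
#' sim <- simulate_policy(example_problem(), sol$policy, n_traj = 2000, seed = 1)
#' glance(sim)
#' @export
simulate_policy <- function(problem, policy, n_traj = 10000L, seed = 1L,
                            semantics = c("delayed", "immediate")) {
  semantics <- match.arg(semantics)
  net <- problem$network
  K <- problem$costs$horizon
  cm <- cost_matrices(net, problem$costs)
  if (inherits(policy, "pbn_policy") || (is.data.frame(policy) && "action" %in% names(policy))) {
    timing <- attr(policy, "timing") %||% "direct"
    semantics <- attr(policy, "semantics") %||% semantics
    lookup <- policy_lookup(policy)
    u0 <- attr(policy, "u0")
  } else if (is.function(policy)) {
    timing <- "direct"
    fn <- policy
    lookup <- function(t, base_idx, u_code, st) bits_to_code(as_control(net, fn(t, st)))
    u0 <- NULL
  } else {
    stop("policy must be a solution policy tibble or a function(t, state)", call. = FALSE)
  }
  ctx <- kernel_context(net, semantics)
  base0 <- encode_state(net, problem$x0, problem$d0, problem$s0, problem$per0)

  samples <- withr::with_seed(as.integer(seed), {
    cost <- numeric(n_traj)
    base <- rep(base0, n_traj)
    ucur <- if (timing == "input") {
      rep(u0 %||% lookup(0L, base0, NA_integer_, decode_state(net, base0)), n_traj)
    } else NULL
    for (t in seq_len(K) - 1L) {
      nb <- integer(n_traj)
      nu <- if (timing == "input") integer(n_traj) else NULL
      groups <- if (timing == "input") split(seq_len(n_traj), paste(base, ucur)) else
        split(seq_len(n_traj), base)
      for (g in groups) {
        b <- base[g[1]]
        st <- decode_state(net, b)
        uc <- if (timing == "input") ucur[g[1]] else lookup(t, b, NA_integer_, st)
        cost[g] <- cost[g] + cm$g[bits_to_code(st$x) + 1L, uc + 1L]
        succ <- kernel_succ(ctx, b, uc)
        draw <- if (length(succ$idx) == 1L) rep(1L, length(g)) else
          sample.int(length(succ$idx), length(g), replace = TRUE, prob = succ$prob)
        nb[g] <- succ$idx[draw]
        if (timing == "input") nu[g] <- lookup(t, b, uc, st)
      }
      base <- nb
      if (timing == "input") ucur <- nu
    }
    xcodes <- vapply(base, function(b) bits_to_code(decode_state(net, b)$x), numeric(1))
    cost + cm$gK[xcodes + 1L]
  })
  structure(list(
    samples = samples,
    mean = mean(samples),
    se = stats::sd(samples) / sqrt(n_traj),
    n_traj = as.integer(n_traj),
    seed = as.integer(seed),
    semantics = semantics
  ), class = "pbn_simulation")
}

#' @export
print.pbn_simulation <- function(x, ...) {
  cat(sprintf("<pbn_simulation> %d trajectories (seed %d): mean cost %s, SE %s\n",
              x$n_traj, x$seed, format(x$mean, digits = 10), format(x$se, digits = 4)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pbn_simulation <- function(x, ...) {
  tibble::tibble(mean = x$mean, se = x$se, n_traj = x$n_traj, seed = x$seed,
                 semantics = x$semantics)
}

#' @exportS3Method generics::tidy
tidy.pbn_simulation <- function(x, ...) {
  tibble::tibble(trajectory = seq_along(x$samples), cost = x$samples)
}
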