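# Generic finite MDPs with reward structures, and the minimum
# reachability-reward solver.
#
# An MDP here is (S, alpha, delta) with a state reward rho and an action
# reward tau.  R_min[F T] -- the minimum expected reward cumulated until the
# target set T is first reached -- satisfies the fixed point
#   v_s = 0                                         for s in T,
#   v_s = rho(s) + min_a ( tau(s, a) + sum_s' delta(s,a)(s') v_s' )  else,
# and is infinite exactly where no resolution of the nondeterminism reaches
# T almost surely.  The infinite states are found by a graph fixpoint (the
# classical "exists an adversary reaching T with probability 1" double
# fixpoint), never by watching the iteration diverge.

#' Construct a finite MDP with rewards
#'
#' Low-level container used by the time-augmented reduction and by the
#' interpreter of generated model-checker code; also usable directly.
#'
#' @param actions A list with one entry per state; each entry is a list of
#'   actions, each action a list with elements `label` (character), `dest`
#'   (integer vector of successor states), `prob` (numeric vector summing
#'   to one) and `reward` (action reward, default 0).  Actions must be
#'   ordered by label; the solver breaks ties toward the first action.
#' @param state_reward Numeric vector of state rewards (default all zero).
#' @param target Integer vector of target state indices.
#' @param init Integer vector of initial state indices.
#' @param states Optional tibble of state annotations (one row per state).
#' @return A `pbn_mdp` object.
#' @export
new_mdp <- function(actions, state_reward = NULL, target = integer(), init = 1L,
                    states = NULL) {
  ns <- length(actions)
  # drop zero-probability branches so Inf values never meet 0 * Inf
  actions <- lapply(actions, function(as) lapply(as, function(a) {
    if (is.null(a$reward)) a$reward <- 0
    keep <- a$prob > 0
    a$dest <- a$dest[keep]; a$prob <- a$prob[keep]
    if (!is.null(a$dec)) a$dec <- a$dec[keep]
    a
  }))
  if (is.null(state_reward)) state_reward <- rep(0, ns)
  structure(list(
    n_states = ns, actions = actions, state_reward = state_reward,
    target = as.integer(target), init = as.integer(init), states = states
  ), class = "pbn_mdp")
}

#' @export
print.pbn_mdp <- function(x, ...) {
  na <- sum(vapply(x$actions, length, integer(1)))
  cat(sprintf("<pbn_mdp> %d states, %d state-action pairs, %d target state(s)\n",
              x$n_states, na, length(x$target)))
  invisible(x)
}

# States from which some resolution of the nondeterminism reaches the
# target with probability 1 (Prob1E double fixpoint).
prob1e <- function(mdp) {
  ns <- mdp$n_states
  in_t <- rep(FALSE, ns); in_t[mdp$target] <- TRUE
  X <- rep(TRUE, ns)
  repeat {
    Y <- in_t
    repeat {
      grow <- FALSE
      for (s in which(!Y)) {
        for (a in mdp$actions[[s]]) {
          if (all(X[a$dest]) && any(Y[a$dest])) {
            Y[s] <- TRUE; grow <- TRUE; break
          }
        }
      }
      if (!grow) break
    }
    if (identical(Y, X)) break
    X <- Y
  }
  X
}

#' Minimum reachability reward
#'
#' Computes `R_min[F target]`: per state, the minimum (over deterministic
#' memoryless resolutions of the nondeterminism, which suffice) expected
#' reward cumulated until the target set is first reached.  States from
#' which no resolution reaches the target almost surely get `Inf`, detected
#' by a graph precomputation.  Finite values are found by value iteration
#' (Jacobi sweeps from zero), which for time-augmented models terminates
#' exactly.
#'
#' @param mdp A [new_mdp()] object.
#' @param tol Convergence tolerance on the sup-norm of the update.
#' @param max_iter Iteration cap.
#' @return A list with `value` (numeric vector, `Inf` allowed), `policy`
#'   (index of the greedy action per state, `NA` on targets), `iterations`
#'   and `residual` (final Bellman residual over finite states).
#' @examples
#' # two-state chain: s1 -> target with action reward 1
#' m <- new_mdp(
#'   actions = list(
#'     list(list(label = "go", dest = 2L, prob = 1, reward = 1)),
#'     list(list(label = "stay", dest = 2L, prob = 1, reward = 0))
#'   ),
#'   target = 2L
#' )
#' min_reachability_reward(m)$value
#' @export
min_reachability_reward <- function(mdp, tol = 1e-12, max_iter = 100000L) {
  ns <- mdp$n_states
  ok <- prob1e(mdp)
  v <- rep(0, ns)
  v[!ok] <- Inf
  is_t <- rep(FALSE, ns); is_t[mdp$target] <- TRUE
  active <- which(ok & !is_t)
  it <- 0L
  repeat {
    it <- it + 1L
    vn <- v
    for (s in active) {
      best <- Inf
      for (a in mdp$actions[[s]]) {
        q <- a$reward + sum(a$prob * v[a$dest])
        if (q < best) best <- q
      }
      vn[s] <- mdp$state_reward[s] + best
    }
    delta <- max(0, abs(vn[active] - v[active]))
    v <- vn
    if (delta <= tol || it >= max_iter) break
  }
  pol <- rep(NA_integer_, ns)
  for (s in active) {
    qs <- vapply(mdp$actions[[s]], function(a) a$reward + sum(a$prob * v[a$dest]),
                 numeric(1))
    pol[s] <- which.min(qs)
  }
  res <- 0
  for (s in active) {
    qs <- vapply(mdp$actions[[s]], function(a) a$reward + sum(a$prob * v[a$dest]),
                 numeric(1))
    res <- max(res, abs(v[s] - (mdp$state_reward[s] + min(qs))))
  }
  list(value = v, policy = pol, iterations = it, residual = res)
}
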