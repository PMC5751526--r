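# Reduction of finite-horizon optimal control to minimum reachability
# reward: the time-augmented MDP.
#
# The model state space S is crossed with a step counter t in [0..K+1];
# transitions advance t up to K+1 and stay there; the target is
# T' = { (s, K+1) }.  Rewards are restricted so that the reachability
# reward equals the finite-horizon cost: the action reward tau' charges the
# control cost g(x, u) at steps 0..K-1, and the state reward rho' charges
# the terminal cost g_K(x) exactly on the t = K layer.
#
# Two control timings are supported:
#
# * "input" (default): the control input is part of the dynamic state, as
#   in the generated synchronous module code, where an INPUT module sets
#   the next step's control during each transition.  The action chooses
#   u(t+1); u(0) is an initial condition (the unconstrained optimum
#   minimizes over it).  The control cost charged on a transition is that
#   of the control currently in effect.
# * "direct": the textbook reduction; the action is the control applied in
#   the same step, so a policy mu_t observes the full state at time t.
#
# Hard constraints H bound how often each control input may be applied;
# counters ct_i ride along in the augmented state and actions that would
# exceed a bound are removed (u = 0 is always allowed, so action sets stay
# nonempty).

#' Build the time-augmented MDP of a control problem
#'
#' @param problem A [control_problem()].
#' @param constraints Optional integer vector of upper bounds `H_i` (one
#'   per control input) on the number of times each control may be applied.
#' @param timing `"input"` (control input carried in the state and chosen
#'   one synchronous transition ahead, faithful to the generated module
#'   code) or `"direct"` (control applied in the same step it is chosen).
#' @param semantics Kernel semantics, see [step_distribution()].
#' @param forced_u0 Optional control vector fixing the control in effect at
#'   step 0.
#' @return A [new_mdp()] whose `states` tibble carries `t`, `x`, `d`, `s`,
#'   `per` (plus `u` under input timing and `ct` when constrained), with
#'   construction metadata in attribute `info`.  Only states reachable from
#'   the initial condition are included.
#' @export
build_augmented_mdp <- function(problem, constraints = NULL,
                                timing = c("input", "direct"),
                                semantics = c("delayed", "immediate"),
                                forced_u0 = NULL) {
  timing <- match.arg(timing)
  semantics <- match.arg(semantics)
  net <- problem$network
  K <- problem$costs$horizon
  m <- n_controls(net)
  ctx <- kernel_context(net, semantics)
  cm <- cost_matrices(net, problem$costs)
  H <- check_constraints(constraints, m, K)
  base0 <- encode_state(net, problem$x0, problem$d0, problem$s0, problem$per0)
  u_codes <- if (m == 0L) 0L else 0:(2^m - 1)

  key_of <- function(tup) paste(c(tup$base, tup$u, tup$ct), collapse = "_")
  ord_of <- function(tup) {
    o <- tup$base
    if (timing == "input") o <- (o - 1) * 2^m + tup$u
    if (!is.null(H)) for (h in tup$ct) o <- o * (K + 2) + h
    o
  }

  init_tuples <- if (timing == "input") {
    u0s <- if (is.null(forced_u0)) u_codes else bits_to_code(as_control(net, forced_u0))
    lapply(u0s, function(u0) {
      list(base = base0, u = u0, ct = if (is.null(H)) NULL else rep(0L, m))
    })
  } else {
    list(list(base = base0, u = NULL, ct = if (is.null(H)) NULL else rep(0L, m)))
  }
  if (!is.null(H) && timing == "input" && K > 0L) {
    ok0 <- vapply(init_tuples, function(tp) all(code_to_bits(tp$u, m) <= H), logical(1))
    if (!any(ok0)) stop("forced initial control violates the hard constraints", call. = FALSE)
    init_tuples <- init_tuples[ok0]
  }

  # ---- discover layers ------------------------------------------------
  layer_tuples <- vector("list", K + 2L)
  layer_tuples[[1L]] <- init_tuples
  succ_layer <- function(tuples, t) {
    seen <- new.env(parent = emptyenv())
    out <- list()
    for (tup in tuples) {
      for (a in augmented_actions(tup, t, K, m, H, timing, forced_u0, net, u_codes)) {
        succ <- kernel_succ(ctx, tup$base, a$u_applied)
        for (jj in seq_along(succ$idx)) {
          dtp <- list(base = succ$idx[jj], u = a$u_next, ct = a$ct_next)
          kk <- key_of(dtp)
          if (is.null(seen[[kk]])) {
            seen[[kk]] <- TRUE
            out[[length(out) + 1L]] <- dtp
          }
        }
      }
    }
    out
  }
  for (t in 0:(K - 1)) {
    if (K == 0L) break
    layer_tuples[[t + 2L]] <- succ_layer(layer_tuples[[t + 1L]], t)
  }
  # the absorbing t = K+1 layer: successors of layer K, closed within itself
  lastK1 <- succ_layer(layer_tuples[[K + 1L]], K)
  repeat {
    have <- vapply(lastK1, key_of, character(1))
    more <- succ_layer(lastK1, K + 1L)
    new <- more[!vapply(more, key_of, character(1)) %in% have]
    if (length(new) == 0L) break
    lastK1 <- c(lastK1, new)
  }
  layer_tuples[[K + 2L]] <- lastK1

  # ---- assign canonical ids ------------------------------------------
  states <- list()
  idmaps <- vector("list", K + 2L)
  for (t in 0:(K + 1L)) {
    tuples <- layer_tuples[[t + 1L]]
    tuples <- tuples[order(vapply(tuples, ord_of, numeric(1)))]
    idmap <- new.env(parent = emptyenv())
    for (tup in tuples) {
      gid <- length(states) + 1L
      states[[gid]] <- c(tup, list(t = t, gid = gid))
      idmap[[key_of(tup)]] <- gid
    }
    layer_tuples[[t + 1L]] <- tuples
    idmaps[[t + 1L]] <- idmap
  }

  # ---- transitions ----------------------------------------------------
  actions <- vector("list", length(states))
  for (st in states) {
    t <- st$t
    dest_map <- idmaps[[min(t + 1L, K + 1L) + 1L]]
    acts <- augmented_actions(st, t, K, m, H, timing, forced_u0, net, u_codes)
    actions[[st$gid]] <- lapply(acts, function(a) {
      succ <- kernel_succ(ctx, st$base, a$u_applied)
      dd <- vapply(seq_along(succ$idx), function(jj) {
        dest_map[[paste(c(succ$idx[jj], a$u_next, a$ct_next), collapse = "_")]]
      }, integer(1))
      oo <- order(dd)
      xr <- bits_to_code(decode_state(net, st$base)$x) + 1L
      list(label = a$label, dest = dd[oo], prob = succ$prob[oo], dec = succ$dec[oo],
           reward = if (t <= K - 1L) cm$g[xr, a$u_applied + 1L] else 0,
           reward_str = if (t <= K - 1L) cm$g_str[xr, a$u_applied + 1L] else "0",
           u_applied = a$u_applied)
    })
  }

  ns <- length(states)
  rho <- numeric(ns)
  rho_str <- rep("0", ns)
  for (st in states) {
    if (st$t == K) {
      xc <- bits_to_code(decode_state(net, st$base)$x) + 1L
      rho[st$gid] <- cm$gK[xc]
      rho_str[st$gid] <- cm$gK_str[xc]
    }
  }

  dec_list <- lapply(states, function(st) decode_state(net, st$base))
  srows <- tibble::tibble(
    id = vapply(states, `[[`, integer(1), "gid"),
    t = vapply(states, `[[`, integer(1), "t"),
    x = vapply(dec_list, function(b) bits_to_string(b$x), character(1)),
    d = vapply(dec_list, function(b) paste(b$d, collapse = ","), character(1)),
    s = vapply(dec_list, `[[`, integer(1), "s"),
    per = vapply(dec_list, function(b) bits_to_string(b$per), character(1)),
    x_decimal = vapply(dec_list, function(b) bits_to_code(b$x), numeric(1))
  )
  if (timing == "input") {
    srows$u <- vapply(states, function(st) bits_to_string(code_to_bits(st$u, m)),
                      character(1))
  }
  if (!is.null(H)) {
    srows$ct <- vapply(states, function(st) paste(st$ct, collapse = ","), character(1))
  }
  mdp <- new_mdp(actions, state_reward = rho,
                 target = vapply(layer_tuples[[K + 2L]],
                                 function(tp) idmaps[[K + 2L]][[key_of(tp)]], integer(1)),
                 init = vapply(layer_tuples[[1L]],
                               function(tp) idmaps[[1L]][[key_of(tp)]], integer(1)),
                 states = tibble::as_tibble(srows))
  attr(mdp, "info") <- list(
    timing = timing, semantics = semantics, K = K, constraints = H,
    forced_u0 = forced_u0, problem = problem, rho_str = rho_str
  )
  mdp
}

check_constraints <- function(constraints, m, K) {
  if (is.null(constraints)) return(NULL)
  H <- as.integer(constraints)
  if (length(H) != m || any(H < 0L) || any(H > K)) {
    stop("constraints must give one bound in [0..K] per control input", call. = FALSE)
  }
  H
}

# The action set of one augmented state.  Each action records the control
# code applied during this transition (u_applied), the control code carried
# into the successor state (u_next, input timing), and the successor
# counters.  Actions are ordered by ascending control code so that value
# ties break toward "no control".
augmented_actions <- function(tup, t, K, m, H, timing, forced_u0, net, u_codes) {
  charged <- t <= K - 1L    # control applied at steps 0..K-1 counts
  out <- list()
  if (timing == "input") {
    u_applied <- tup$u
    ct_next <- tup$ct
    if (!is.null(H) && charged) ct_next <- pmin(tup$ct + code_to_bits(u_applied, m), K)
    for (a in u_codes) {
      if (!is.null(H) && (t + 1L) <= K - 1L &&
          any(ct_next + code_to_bits(a, m) > H)) next
      out[[length(out) + 1L]] <- list(
        label = bits_to_string(code_to_bits(a, m)),
        u_applied = u_applied, u_next = a, ct_next = ct_next
      )
    }
  } else {
    for (a in u_codes) {
      ct_next <- tup$ct
      if (!is.null(H) && charged) {
        ct_next <- tup$ct + code_to_bits(a, m)
        if (any(ct_next > H)) next
      }
      if (t == 0L && !is.null(forced_u0) &&
          a != bits_to_code(as_control(net, forced_u0))) next
      out[[length(out) + 1L]] <- list(
        label = bits_to_string(code_to_bits(a, m)),
        u_applied = a, u_next = NULL, ct_next = ct_next
      )
    }
  }
  out
}
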