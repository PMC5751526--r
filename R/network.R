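# CS-PBNp model objects: networks, costs, control problems.

#' Candidate function set for one gene
#'
#' Bundles the candidate Boolean predictor functions of a gene with their
#' selection probabilities.  Expressions are parsed when the node is
#' assembled into a [pbn_network()].
#'
#' @param exprs Character vector of Boolean expressions (see [parse_expr()]).
#' @param probs Selection probabilities, one per expression; must sum to 1.
#'   May be numeric or decimal strings (`"0.3"`); strings are kept exact.
#' @return A `pbn_node` list.
#' @examples
#' pbn_node(c("x1 | u", "x1 & x2"), c(0.3, 0.7))
#' @export
pbn_node <- function(exprs, probs) {
  if (length(exprs) < 1L) stop("a gene needs at least one candidate function", call. = FALSE)
  if (length(exprs) != length(probs)) {
    stop("need one selection probability per candidate function", call. = FALSE)
  }
  structure(list(
    expr_text = as.character(exprs),
    prob_str = vapply(probs, dec_str, character(1)),
    probs = vapply(probs, function(p) dec_to_num(as_dec(p)), numeric(1))
  ), class = "pbn_node")
}

#' Define a context-sensitive probabilistic Boolean network with perturbation
#'
#' A CS-PBNp over `n` genes assigns each gene a set of candidate Boolean
#' predictor functions with selection probabilities `c_j^(i)`.  The selected
#' function indices (the *context* `d`) persist between steps; a global
#' switch event with probability `q` resamples them.  Independently, each
#' gene is perturbed with probability `p`, which flips its value instead of
#' applying its predictor.  Switch and perturbation indicators are sampled
#' one step ahead and carried in the state, mirroring the synchronous
#' module encoding used for model-checker export (see
#' `vignette("pbn-control")`).
#'
#' @param genes Character vector of gene names, or a single integer `n`
#'   (names default to `x1..xn`).
#' @param controls Character vector of control input names, or an integer
#'   `m` (`m = 1` is named `"u"`, otherwise `u1..um`); may be 0.
#' @param nodes List of [pbn_node()] objects, one per gene, in gene order.
#' @param q Switching probability in `[0, 1]`.
#' @param p Perturbation probability in `[0, 1]`.
#' @return A `pbn_network` object.
#' @examples
#' net <- pbn_network(
#'   genes = 2, controls = 1,
#'   nodes = list(
#'     pbn_node(c("x1 | u", "x1 & x2"), c(0.3, 0.7)),
#'     pbn_node(c("x1 & !u", "x2"), c(0.2, 0.8))
#'   ),
#'   q = 0.3, p = 0.1
#' )
#' net
#' n_constituent_networks(net)
#' @export
pbn_network <- function(genes, controls = 0, nodes, q, p) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- paste0("x", seq_len(genes))
  }
  if (is.numeric(controls) && length(controls) == 1L) {
    controls <- if (controls == 0) character() else if (controls == 1) "u" else
      paste0("u", seq_len(controls))
  }
  if (length(genes) < 1L) stop("need at least one gene", call. = FALSE)
  if (length(nodes) != length(genes)) {
    stop("need one pbn_node per gene", call. = FALSE)
  }
  net <- structure(list(
    genes = as.character(genes),
    controls = as.character(controls),
    nodes = nodes,
    q = dec_to_num(as_dec(q)), q_str = dec_str(q),
    p = dec_to_num(as_dec(p)), p_str = dec_str(p)
  ), class = "pbn_network")
  for (i in seq_along(net$nodes)) {
    net$nodes[[i]]$exprs <- lapply(net$nodes[[i]]$expr_text, parse_expr, network = net)
    net$nodes[[i]]$expr_text <- vapply(net$nodes[[i]]$exprs, format, character(1))
  }
  net
}

n_genes <- function(net) length(net$genes)
n_controls <- function(net) length(net$controls)
n_funs <- function(net) vapply(net$nodes, function(nd) length(nd$exprs), integer(1))

#' Number of constituent Boolean networks
#'
#' The product of the candidate-function counts over all genes: the number
#' of deterministic Boolean networks the probabilistic network mixes over.
#'
#' @param network A [pbn_network()].
#' @return A number.
#' @export
n_constituent_networks <- function(network) prod(n_funs(network))

#' @export
print.pbn_network <- function(x, ...) {
  cat(sprintf("<pbn_network> %d gene(s), %d control input(s), q = %s, p = %s\n",
              n_genes(x), n_controls(x), x$q_str, x$p_str))
  for (i in seq_along(x$genes)) {
    nd <- x$nodes[[i]]
    for (j in seq_along(nd$exprs)) {
      cat(sprintf("  %s <- %-30s c = %s\n", x$genes[i], nd$expr_text[j], nd$prob_str[j]))
    }
  }
  cat(sprintf("  %d constituent Boolean network(s)\n", n_constituent_networks(x)))
  invisible(x)
}

#' Define control and terminal costs with a horizon
#'
#' Costs are sparse tables with a default of 0 for unlisted entries.  The
#' control cost `g(x, u)` is charged at each of the `K` control steps; the
#' terminal cost `g_K(x)` is charged on the state reached after `K` steps.
#'
#' @param control Data frame with columns `u` (control bits as a binary
#'   string, MSB = first control) and `cost`, optionally `x` (gene bits,
#'   `NA` matching any state).  May be `NULL` for zero control cost.
#' @param terminal Data frame with columns `x` (gene bits, MSB = x1) and
#'   `cost`.  May be `NULL` for zero terminal cost.
#' @param horizon Number of control steps `K` (a nonnegative integer).
#' @param default Cost of unlisted entries (0, as usual).
#' @return A `pbn_costs` object.
#' @examples
#' cost_spec(
#'   control = data.frame(u = "1", cost = 1),
#'   terminal = data.frame(x = c("01", "10", "11"), cost = c(2, 4, 6)),
#'   horizon = 4
#' )
#' @export
cost_spec <- function(control = NULL, terminal = NULL, horizon, default = 0) {
  tidy_tab <- function(df, need, opt = character()) {
    if (is.null(df)) {
      return(tibble::as_tibble(stats::setNames(
        rep(list(character(0)), length(c(need, opt))), c(need, opt)
      )))
    }
    df <- tibble::as_tibble(df)
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("cost table misses column(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    for (o in opt) if (!o %in% names(df)) df[[o]] <- NA_character_
    df
  }
  ctrl <- tidy_tab(control, c("u", "cost"), "x")
  term <- tidy_tab(terminal, c("x", "cost"))
  ctrl$cost <- as.numeric(ctrl$cost)
  term$cost <- as.numeric(term$cost)
  fmt <- function(v) vapply(v, dec_str, character(1))
  if (nrow(ctrl)) ctrl$cost_str <- fmt(ctrl$cost) else ctrl$cost_str <- character(0)
  if (nrow(term)) term$cost_str <- fmt(term$cost) else term$cost_str <- character(0)
  structure(list(
    control = ctrl[c("x", "u", "cost", "cost_str")],
    terminal = term[c("x", "cost", "cost_str")],
    default = dec_to_num(as_dec(default)),
    default_str = dec_str(default),
    horizon = as.integer(horizon)
  ), class = "pbn_costs")
}

#' @export
print.pbn_costs <- function(x, ...) {
  cat(sprintf("<pbn_costs> horizon K = %d, default cost %s\n", x$horizon, x$default_str))
  if (nrow(x$control)) {
    cat("  control cost:\n")
    for (i in seq_len(nrow(x$control))) {
      cat(sprintf("    u = %s%s : %s\n", x$control$u[i],
                  ifelse(is.na(x$control$x[i]), "", paste0(", x = ", x$control$x[i])),
                  x$control$cost_str[i]))
    }
  }
  if (nrow(x$terminal)) {
    cat("  terminal cost:\n")
    for (i in seq_len(nrow(x$terminal))) {
      cat(sprintf("    x = %s : %s\n", x$terminal$x[i], x$terminal$cost_str[i]))
    }
  }
  invisible(x)
}

# dense lookup tables; rows x_code+1, cols u_code+1
cost_matrices <- function(network, costs) {
  n <- n_genes(network)
  m <- n_controls(network)
  g <- matrix(costs$default, nrow = 2^n, ncol = 2^m)
  g_str <- matrix(costs$default_str, nrow = 2^n, ncol = 2^m)
  if (nrow(costs$control)) {
    for (i in seq_len(nrow(costs$control))) {
      uc <- bits_to_code(string_to_bits(costs$control$u[i])) + 1L
      xs <- if (is.na(costs$control$x[i])) seq_len(2^n) else
        bits_to_code(string_to_bits(costs$control$x[i])) + 1L
      g[xs, uc] <- costs$control$cost[i]
      g_str[xs, uc] <- costs$control$cost_str[i]
    }
  }
  gK <- rep(costs$default, 2^n)
  gK_str <- rep(costs$default_str, 2^n)
  if (nrow(costs$terminal)) {
    for (i in seq_len(nrow(costs$terminal))) {
      xc <- bits_to_code(string_to_bits(costs$terminal$x[i])) + 1L
      gK[xc] <- costs$terminal$cost[i]
      gK_str[xc] <- costs$terminal$cost_str[i]
    }
  }
  list(g = g, g_str = g_str, gK = gK, gK_str = gK_str)
}

#' Assemble a finite-horizon control problem
#'
#' @param network A [pbn_network()].
#' @param costs A [cost_spec()].
#' @param x0 Initial gene state: binary string (MSB = x1) or 0/1 vector.
#' @param d0 Initial context: integer vector of selected function indices,
#'   one per gene (defaults to 1 for every gene).
#' @param s0 Initial switch indicator (default 0: no switch pending).
#' @param per0 Initial perturbation indicators (default all 0).
#' @return A `pbn_problem` object.
#' @examples
#' prob <- example_problem()
#' prob
#' @export
control_problem <- function(network, costs, x0, d0 = NULL, s0 = 0L, per0 = NULL) {
  n <- n_genes(network)
  x0 <- if (is.character(x0)) string_to_bits(x0) else as.integer(x0)
  if (length(x0) != n || !all(x0 %in% 0:1)) {
    stop("x0 must give one 0/1 value per gene", call. = FALSE)
  }
  if (is.null(d0)) d0 <- rep(1L, n)
  d0 <- as.integer(d0)
  l <- n_funs(network)
  if (length(d0) != n || any(d0 < 1L | d0 > l)) {
    stop("d0 must select a candidate function index for every gene", call. = FALSE)
  }
  if (is.null(per0)) per0 <- rep(0L, n)
  per0 <- if (is.character(per0)) string_to_bits(per0) else as.integer(per0)
  if (length(per0) != n || !all(per0 %in% 0:1)) {
    stop("per0 must give one 0/1 value per gene", call. = FALSE)
  }
  structure(list(
    network = network, costs = costs,
    x0 = x0, d0 = d0, s0 = as.integer(s0), per0 = per0
  ), class = "pbn_problem")
}

#' @export
print.pbn_problem <- function(x, ...) {
  cat("<pbn_problem>\n")
  print(x$network)
  print(x$costs)
  cat(sprintf("  initial: x = %s, d = (%s), s = %d, per = %s\n",
              bits_to_string(x$x0), paste(x$d0, collapse = ","), x$s0,
              bits_to_string(x$per0)))
  invisible(x)
}

#' Validate a network (and optionally costs) against the model invariants
#'
#' Reports every violated invariant: probabilities out of `[0, 1]`,
#' selection probabilities not summing to one (checked exactly for decimal
#' input, to `1e-9` otherwise), negative costs, malformed cost-table keys.
#'
#' @param network A [pbn_network()].
#' @param costs Optional [cost_spec()].
#' @return A tibble with columns `component`, `field`, `message`; zero rows
#'   if and only if the specification is valid.
#' @examples
#' validate_spec(example_network())
#' @export
validate_spec <- function(network, costs = NULL) {
  bad <- list()
  note <- function(component, field, message) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      component = component, field = field, message = message
    )
  }
  for (nm in c("q", "p")) {
    v <- network[[nm]]
    if (!is.finite(v) || v < 0 || v > 1) {
      note("network", nm, sprintf("%s = %s outside [0, 1]", nm, format(v)))
    }
  }
  if (n_genes(network) < 1L) note("network", "genes", "no genes")
  if (anyDuplicated(c(network$genes, network$controls))) {
    note("network", "names", "duplicated gene/control names")
  }
  for (i in seq_along(network$nodes)) {
    nd <- network$nodes[[i]]
    lab <- sprintf("nodes[%d]", i)
    if (length(nd$exprs) < 1L) note("network", lab, "no candidate functions")
    if (any(nd$probs < 0 | nd$probs > 1)) {
      note("network", lab, "selection probability outside [0, 1]")
    }
    s <- dec_sum(lapply(nd$prob_str, dec_parse))
    if (dec_cmp(s, dec_one()) != 0) {
      # decimal strings are exact; numeric input was canonicalized at 15
      # significant digits, so re-check with a float tolerance before flagging
      if (abs(sum(nd$probs) - 1) > 1e-9) {
        note("network", lab, sprintf("selection probabilities sum to %s", dec_format(s)))
      }
    }
  }
  if (!is.null(costs)) {
    if (is.na(costs$horizon) || costs$horizon < 0L) {
      note("costs", "horizon", "horizon must be a nonnegative integer")
    }
    chk_bits <- function(s, len, lab) {
      ok <- grepl("^[01]+$", s) & nchar(s) == len
      if (!all(ok)) note("costs", lab, sprintf("bad state key '%s'", s[!ok][1]))
    }
    if (nrow(costs$control)) {
      if (any(costs$control$cost < 0)) note("costs", "control", "negative control cost")
      chk_bits(costs$control$u, n_controls(network), "control$u")
      xs <- costs$control$x[!is.na(costs$control$x)]
      if (length(xs)) chk_bits(xs, n_genes(network), "control$x")
    }
    if (nrow(costs$terminal)) {
      if (any(costs$terminal$cost < 0)) note("costs", "terminal", "negative terminal cost")
      chk_bits(costs$terminal$x, n_genes(network), "terminal$x")
    }
    if (costs$default < 0) note("costs", "default", "negative default cost")
  }
  if (length(bad) == 0L) {
    tibble::tibble(component = character(), field = character(), message = character())
  } else {
    dplyr::bind_rows(bad)
  }
}

#' The two-gene example network
#'
#' The small CS-PBNp used throughout the documentation and tests: two genes,
#' one control input, `q = 0.3`, `p = 0.1`, with gene 1 updated by
#' `x1 | u` (0.3) or `x1 & x2` (0.7) and gene 2 by `x1 & !u` (0.2) or
#' `x2` (0.8).
#'
#' @return A [pbn_network()].
#' @export
example_network <- function() {
  pbn_network(
    genes = 2, controls = 1,
    nodes = list(
      pbn_node(c("x1 | u", "x1 & x2"), c("0.3", "0.7")),
      pbn_node(c("x1 & !u", "x2"), c("0.2", "0.8"))
    ),
    q = "0.3", p = "0.1"
  )
}

#' The example control problem
#'
#' The [example_network()] with unit control cost for `u = 1`, terminal
#' costs 0/2/4/6 for gene states 00/01/10/11, horizon `K = 4`, started in
#' `x = 11` with the first candidate function selected for both genes,
#' switch off and no perturbation pending.
#'
#' @param horizon Control horizon (default 4).
#' @return A `pbn_problem`.
#' @export
example_problem <- function(horizon = 4) {
  control_problem(
    example_network(),
    cost_spec(
      control = data.frame(u = "1", cost = 1),
      terminal = data.frame(x = c("00", "01", "10", "11"), cost = c(0, 2, 4, 6)),
      horizon = horizon
    ),
    x0 = "11", d0 = c(1, 1), s0 = 0, per0 = "00"
  )
}

#' Generate a random CS-PBNp instance
#'
#' Draws a reproducible random network for property tests and benchmarks:
#' random Boolean expressions over at most `max_indegree` gene variables
#' (each possibly involving one control input), and selection probabilities
#' drawn as a random composition of `prob_denom` into positive parts, so the
#' stored probabilities are exact decimals summing to one exactly.
#'
#' @param n,m Gene and control counts.
#' @param max_indegree Maximum number of distinct gene variables per function.
#' @param l Candidate functions per gene (scalar or length-`n` vector).
#' @param q,p Switching and perturbation probabilities.
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @param prob_denom Denominator of the selection-probability composition;
#'   10 gives tenths, 8 gives exactly representable dyadic weights.
#' @return A [pbn_network()].
#' @examples
#' random_network(n = 2, m = 1, l = 2, q = 0.2, p = 0.1, seed = 7)
#' @export
random_network <- function(n, m = 1, max_indegree = 2, l = 2, q = 0.1, p = 0.05,
                           seed = NULL, prob_denom = 10) {
  if (n < 1 || m < 0 || any(l < 1)) stop("invalid sizes", call. = FALSE)
  draw <- function() {
    genes <- paste0("x", seq_len(n))
    controls <- if (m == 0) character() else if (m == 1) "u" else paste0("u", seq_len(m))
    lv <- rep_len(l, n)
    nodes <- lapply(seq_len(n), function(i) {
      exprs <- vapply(seq_len(lv[i]), function(j) {
        random_expr_text(genes, controls, max_indegree)
      }, character(1))
      probs <- random_composition(prob_denom, lv[i])
      pbn_node(exprs, probs)
    })
    pbn_network(genes, controls, nodes, q = q, p = p)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_expr_text <- function(genes, controls, max_indegree) {
  k <- sample(seq_len(max(1L, min(max_indegree, length(genes)))), 1L)
  vars <- sample(genes, k)
  if (length(controls) && stats::runif(1) < 0.5) {
    vars <- c(vars, sample(controls, 1L))
  }
  build <- function(vs) {
    if (length(vs) == 1L) {
      v <- vs
      if (stats::runif(1) < 0.3) v <- paste0("!", v)
      return(v)
    }
    cut <- sample(length(vs) - 1L, 1L)
    lhs <- build(vs[seq_len(cut)])
    rhs <- build(vs[-seq_len(cut)])
    op <- sample(c("&", "|"), 1L)
    e <- paste0("(", lhs, " ", op, " ", rhs, ")")
    if (stats::runif(1) < 0.2) e <- paste0("!", e)
    e
  }
  build(sample(vars))
}

# exact composition of denom into k positive parts, returned as decimal strings
random_composition <- function(denom, k) {
  if (k == 1L) return("1")
  if (denom < k) stop("prob_denom must be >= number of candidate functions", call. = FALSE)
  cuts <- sort(sample(denom - 1L, k - 1L))
  parts <- diff(c(0L, cuts, denom))
  den <- as_dec(denom)
  vapply(parts, function(p) {
    # part/denom as an exact decimal; denom is 2^a*5^b by construction
    dec_format(dec_div_pow10_free(as_dec(p), denom))
  }, character(1))
}

# divide an exact decimal by an integer whose only prime factors are 2 and 5
dec_div_pow10_free <- function(d, denom) {
  twos <- 0L; fives <- 0L; rest <- denom
  while (rest %% 2 == 0) { rest <- rest / 2; twos <- twos + 1L }
  while (rest %% 5 == 0) { rest <- rest / 5; fives <- fives + 1L }
  if (rest != 1) stop("prob_denom must have only factors 2 and 5 for exact storage",
                      call. = FALSE)
  k <- max(twos, fives)
  scale <- as_dec(2^(k - twos) * 5^(k - fives))
  num <- dec_mul(d, scale)
  dec_canonical(new_dec(num$limbs, num$exp + k))
}
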