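# Generation of probabilistic model-checker (PRISM) code for a CS-PBNp
# control problem, following the six-step synchronous module encoding:
#
#   1. arithmetize every candidate function into a `formula f{i}{j}`;
#   2. declare the system an `mdp`;
#   3. module SWITCH samples the switch indicator s with probability q;
#   4. module PER{i} samples each perturbation indicator p{i} with
#      probability p;
#   5. module NODE{i} holds x{i} and the context variable d{i}: on a
#      switch the context is resampled and the freshly selected function
#      applied; without a switch the retained function applies; a
#      perturbation flips x{i} instead;
#   6. module INPUT assigns each control input nondeterministically.
#
# A STEP module counts time up to K+1, and a rewards block charges the
# control cost while t <= K-1 and the terminal cost exactly at t = K, so
# that Rmin=? [ F (t=K+1) ] is the optimal expected cost.  Every command
# synchronizes on the label [PBN].  All probability and cost literals are
# the shortest exact decimals of the stored values, so emission is
# byte-stable.

#' Emit PRISM model code for a control problem
#'
#' @inheritParams build_augmented_mdp
#' @param forced_u0 Optional control vector used as the initial value of
#'   the control-input variables (the nondeterministic choice governs
#'   later steps), realizing a forced first action.
#' @return A `pbn_prism` artifact: list with `model` (model source),
#'   `property` (property source) and `manifest` (tibble mapping generated
#'   identifiers and literals to model elements).
#' @examples
#' art <- emit_model(example_problem())
#' cat(substr(art$model, 1, 200))
#' @export
emit_model <- function(problem, constraints = NULL, forced_u0 = NULL) {
  net <- problem$network
  n <- n_genes(net)
  m <- n_controls(net)
  l <- n_funs(net)
  K <- problem$costs$horizon
  H <- check_constraints(constraints, m, K)
  u0_bits <- if (is.null(forced_u0)) rep(0L, m) else as_control(net, forced_u0)
  q_str <- net$q_str
  p_str <- net$p_str
  q1_str <- dec_format(dec_one_minus(dec_parse(q_str)))
  p1_str <- dec_format(dec_one_minus(dec_parse(p_str)))
  gene_names <- paste0("x", seq_len(n))
  ctrl_names <- if (m == 0L) character() else if (m == 1L) "u" else paste0("u", seq_len(m))
  reserved <- c(gene_names, ctrl_names, "s", "t", paste0("d", seq_len(n)),
                paste0("p", seq_len(n)), if (m) paste0("ct", seq_len(m)))
  if (!all(net$genes == gene_names) || (m > 0L && !all(net$controls == ctrl_names))) {
    # generated identifiers are positional; user names must match them or
    # at least not collide
    if (any(c(net$genes, net$controls) %in% setdiff(reserved, c(net$genes, net$controls)))) {
      stop("gene/control names collide with generated identifiers", call. = FALSE)
    }
  }
  man <- list()
  note <- function(kind, name, value) {
    man[[length(man) + 1L]] <<- tibble::tibble(kind = kind, name = name,
                                               value = as.character(value))
  }
  out <- c("mdp;", "")
  # Step 1: formulas
  for (i in seq_len(n)) {
    for (j in seq_len(l[i])) {
      fx <- arithmetize(net$nodes[[i]]$exprs[[j]])
      fx <- rename_vars(fx, net, gene_names, ctrl_names)
      out <- c(out, sprintf("formula f%d%d = %s;", i, j, fx))
      note("formula", sprintf("f%d%d", i, j), fx)
    }
  }
  out <- c(out, "")
  # Step 3: SWITCH
  out <- c(out,
    "module SWITCH",
    sprintf("	s : bool init %s;", if (problem$s0 == 1L) "true" else "false"),
    sprintf("	[PBN] true -> %s : (s'=true) + %s : (s'=false);", q_str, q1_str),
    "endmodule", "")
  note("probability", "q", q_str)
  # Step 4: PER modules
  for (i in seq_len(n)) {
    out <- c(out,
      sprintf("module PER%d", i),
      sprintf("	p%d : [0..1] init %d;", i, problem$per0[i]),
      sprintf("	[PBN] true -> %s : (p%d'=1) + %s : (p%d'=0);", p_str, i, p1_str, i),
      "endmodule", "")
  }
  note("probability", "p", p_str)
  # Step 5: NODE modules
  for (i in seq_len(n)) {
    cs <- net$nodes[[i]]$prob_str
    sel <- function(asgn) {
      if (l[i] == 1L) {
        sprintf("%s & (d%d'=1)", asgn(1L), i)
      } else {
        paste(vapply(seq_len(l[i]), function(j) {
          sprintf("%s : %s & (d%d'=%d)", cs[j], asgn(j), i, j)
        }, character(1)), collapse = " + ")
      }
    }
    cmds <- c(
      sprintf("	[PBN] p%d=0 & s=true -> %s;", i,
              sel(function(j) sprintf("(x%d'=f%d%d)", i, i, j))),
      vapply(seq_len(l[i]), function(j) {
        sprintf("	[PBN] p%d=0 & s=false & d%d=%d -> (x%d'=f%d%d);", i, i, j, i, i, j)
      }, character(1)),
      sprintf("	[PBN] p%d=1 & s=true -> %s;", i,
              sel(function(j) sprintf("(x%d'=1-x%d)", i, i))),
      sprintf("	[PBN] p%d=1 & s=false -> (x%d'=1-x%d);", i, i, i)
    )
    out <- c(out,
      sprintf("module NODE%d", i),
      sprintf("	x%d : [0..1] init %d;", i, problem$x0[i]),
      sprintf("	d%d : [1..%d] init %d;", i, l[i], problem$d0[i]),
      cmds,
      "endmodule", "")
    note("module", sprintf("NODE%d", i), net$genes[i])
    for (j in seq_len(l[i])) note("probability", sprintf("c%d%d", i, j), cs[j])
  }
  # Step 6: INPUT modules
  for (k in seq_len(m)) {
    uk <- if (m == 1L) "u" else sprintf("u%d", k)
    modname <- if (m == 1L) "INPUT" else sprintf("INPUT%d", k)
    out <- c(out,
      sprintf("module %s", modname),
      sprintf("	%s : [0..1] init %d;", uk, u0_bits[k]),
      sprintf("	[PBN] true -> (%s'=0);", uk),
      sprintf("	[PBN] true -> (%s'=1);", uk),
      "endmodule", "")
    note("module", modname, net$controls[k])
    if (!is.null(forced_u0)) note("forced_u0", uk, u0_bits[k])
  }
  # STEP module
  out <- c(out,
    "module STEP",
    sprintf("	t : [0..%d] init 0;", K + 1L),
    sprintf("	[PBN] t<%d -> (t'=t+1);", K + 1L),
    sprintf("	[PBN] t=%d -> (t'=%d);", K + 1L, K + 1L),
    "endmodule", "")
  # counters for hard constraints
  if (!is.null(H)) {
    for (k in seq_len(m)) {
      uk <- if (m == 1L) "u" else sprintf("u%d", k)
      out <- c(out,
        sprintf("module CT%d", k),
        sprintf("	ct%d : [0..%d] init 0;", k, K),
        sprintf("	[PBN] %s=1 & t<=%d & ct%d<%d -> (ct%d'=ct%d+1);", uk, K - 1L, k, K, k, k),
        sprintf("	[PBN] %s=1 & t<=%d & ct%d=%d -> (ct%d'=ct%d);", uk, K - 1L, k, K, k, k),
        sprintf("	[PBN] %s=1 & t>%d -> (ct%d'=ct%d);", uk, K - 1L, k, k),
        sprintf("	[PBN] %s=0 -> (ct%d'=ct%d);", uk, k, k),
        "endmodule", "")
      note("counter", sprintf("ct%d", k), H[k])
    }
  }
  out <- c(out, emit_rewards(problem$costs, K, net), "")
  model <- paste(out, collapse = "\n")
  prop <- emit_property(problem, forced_u0 = forced_u0, constraints = constraints)
  note("property", "Rmin", prop)
  structure(list(model = model, property = prop,
                 manifest = dplyr::bind_rows(man)),
            class = "pbn_prism")
}

# positional identifiers x{i}/u{i} for arbitrary gene names
rename_vars <- function(expr_str, net, gene_names, ctrl_names) {
  map <- c(stats::setNames(gene_names, net$genes),
           if (length(net$controls)) stats::setNames(ctrl_names, net$controls))
  toks <- gregexpr("[A-Za-z_][A-Za-z0-9_]*", expr_str)[[1]]
  if (toks[1] == -1) return(expr_str)
  lens <- attr(toks, "match.length")
  res <- ""
  last <- 1L
  for (k in seq_along(toks)) {
    word <- substr(expr_str, toks[k], toks[k] + lens[k] - 1L)
    res <- paste0(res, substr(expr_str, last, toks[k] - 1L),
                  if (word %in% names(map)) map[[word]] else word)
    last <- toks[k] + lens[k]
  }
  paste0(res, substr(expr_str, last, nchar(expr_str)))
}

#' Emit the rewards block
#'
#' One transition-reward line per control-cost entry, guarded by
#' `t <= K-1`, and one state-reward line per terminal-cost entry, guarded
#' by `t = K`; unlisted combinations are zero by default and omitted.
#'
#' @param costs A [cost_spec()].
#' @param K Horizon.
#' @param network The owning [pbn_network()] (for variable naming).
#' @return Character vector of source lines.
#' @export
emit_rewards <- function(costs, K, network) {
  n <- n_genes(network)
  m <- n_controls(network)
  if (any(costs$control$cost < 0) || any(costs$terminal$cost < 0)) {
    stop("negative cost", call. = FALSE)
  }
  lines <- character()
  uname <- function(k) if (m == 1L) "u" else sprintf("u%d", k)
  for (i in seq_len(nrow(costs$control))) {
    if (costs$control$cost[i] == 0) next
    ub <- string_to_bits(costs$control$u[i])
    guard <- c(sprintf("t<=%d", K - 1L),
               vapply(seq_len(m), function(k) sprintf("%s=%d", uname(k), ub[k]),
                      character(1)))
    if (!is.na(costs$control$x[i])) {
      xb <- string_to_bits(costs$control$x[i])
      guard <- c(guard, sprintf("x%d=%d", seq_len(n), xb))
    }
    lines <- c(lines, sprintf("	[PBN] %s : %s;", paste(guard, collapse = " & "),
                              costs$control$cost_str[i]))
  }
  for (i in seq_len(nrow(costs$terminal))) {
    if (costs$terminal$cost[i] == 0) next
    xb <- string_to_bits(costs$terminal$x[i])
    guard <- c(sprintf("t=%d", K),
               sprintf("x%d=%d", seq_len(n), xb))
    lines <- c(lines, sprintf("	%s : %s;", paste(guard, collapse = " & "),
                              costs$terminal$cost_str[i]))
  }
  if (costs$default != 0) {
    stop("nonzero default costs cannot be emitted sparsely", call. = FALSE)
  }
  c('rewards "cost"', lines, "endrewards")
}

#' Emit the reachability-reward property
#'
#' Unconstrained: `Rmin=? [ F (t=K+1) ]`.  With hard constraints, the
#' target is the conjunction with the counter bounds `ct_i <= H_i`, so any
#' resolution exceeding a bound never reaches the target and is discarded
#' by the minimization.
#'
#' @inheritParams emit_model
#' @return The property source (character scalar).
#' @examples
#' emit_property(example_problem())
#' @export
emit_property <- function(problem, forced_u0 = NULL, constraints = NULL) {
  K <- problem$costs$horizon
  m <- n_controls(problem$network)
  H <- check_constraints(constraints, m, K)
  tgt <- sprintf("t=%d", K + 1L)
  if (!is.null(H)) {
    tgt <- paste(c(tgt, sprintf("ct%d<=%d", seq_len(m), H)), collapse = " & ")
  }
  sprintf("Rmin=? [ F (%s) ]", tgt)
}

#' @export
print.pbn_prism <- function(x, ...) {
  cat("<pbn_prism> model (", length(strsplit(x$model, "\n")[[1]]), " lines), property: ",
      x$property, "\n", sep = "")
  invisible(x)
}

#' Write a PRISM artifact to files
#'
#' Writes `<name>.pm` and `<name>.props` (UTF-8, LF line endings).
#'
#' @param artifact A `pbn_prism` from [emit_model()].
#' @param dir Output directory.
#' @param name Base file name.
#' @return Invisibly, the two paths.
#' @export
write_prism <- function(artifact, dir, name = "model") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pm <- file.path(dir, paste0(name, ".pm"))
  pr <- file.path(dir, paste0(name, ".props"))
  writeLines(artifact$model, pm, sep = "\n", useBytes = TRUE)
  writeLines(artifact$property, pr, sep = "\n", useBytes = TRUE)
  invisible(c(model = pm, property = pr))
}
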