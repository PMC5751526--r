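# Model-file input/output.  A control problem is serialized as YAML or
# JSON (by file extension) with the schema:
#
#   genes:    [x1, x2]            # ordered gene names
#   controls: [u]
#   nodes:                        # one list per gene, in gene order
#     - [{expr: "x1 | u", prob: "0.3"}, {expr: "x1 & x2", prob: "0.7"}]
#     - ...
#   q: "0.3"
#   p: "0.1"
#   costs:
#     control:  [{u: "1", cost: 1}]        # optional x: "11" per entry
#     terminal: [{state: "11", cost: 6}]
#     default: 0
#   horizon: 4
#   initial: {x: "11", d: [1, 1], s: 0, per: "00"}
#
# Gene states are binary strings with MSB = x1.  Probabilities and costs
# may be numbers or strings; strings are kept exact.

#' Read a control problem from a model file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` model file.
#' @return A [control_problem()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    stop("unsupported model-file extension (use .yaml or .json): ", path, call. = FALSE)
  }
  problem_from_list(raw)
}

problem_from_list <- function(raw) {
  need <- function(field, where = "") {
    ptr <- paste0(where, field)
    v <- raw
    for (part in strsplit(ptr, ".", fixed = TRUE)[[1]]) {
      if (is.null(v[[part]])) stop("model file misses /", gsub("\\.", "/", ptr),
                                   call. = FALSE)
      v <- v[[part]]
    }
    v
  }
  genes <- as.character(unlist(need("genes")))
  controls <- as.character(unlist(raw$controls))
  nodes_raw <- need("nodes")
  if (length(nodes_raw) != length(genes)) {
    stop("model file /nodes must list one entry per gene", call. = FALSE)
  }
  nodes <- lapply(seq_along(nodes_raw), function(i) {
    entries <- nodes_raw[[i]]
    if (length(entries) == 0L) stop("model file /nodes[", i, "] is empty", call. = FALSE)
    exprs <- vapply(entries, function(e) {
      if (is.null(e$expr)) stop("model file /nodes[", i, "] entry misses expr",
                                call. = FALSE)
      as.character(e$expr)
    }, character(1))
    probs <- vapply(entries, function(e) {
      if (is.null(e$prob)) stop("model file /nodes[", i, "] entry misses prob",
                                call. = FALSE)
      dec_str(e$prob)
    }, character(1))
    pbn_node(exprs, probs)
  })
  network <- pbn_network(genes, controls, nodes, q = need("q"), p = need("p"))
  costs_raw <- need("costs")
  to_tab <- function(entries, key) {
    if (is.null(entries) || length(entries) == 0L) return(NULL)
    dplyr::bind_rows(lapply(entries, function(e) {
      row <- tibble::tibble(cost = as.numeric(dec_to_num(as_dec(e$cost))))
      if (key == "terminal") {
        if (is.null(e$state)) stop("model file /costs/terminal entry misses state",
                                   call. = FALSE)
        row$x <- as.character(e$state)
      } else {
        if (is.null(e$u)) stop("model file /costs/control entry misses u", call. = FALSE)
        row$u <- as.character(e$u)
        row$x <- if (is.null(e$x)) NA_character_ else as.character(e$x)
      }
      row
    }))
  }
  costs <- cost_spec(
    control = to_tab(costs_raw$control, "control"),
    terminal = to_tab(costs_raw$terminal, "terminal"),
    horizon = need("horizon"),
    default = costs_raw$default %||% 0
  )
  ini <- need("initial")
  problem <- control_problem(
    network, costs,
    x0 = need("initial.x"),
    d0 = if (is.null(ini$d)) NULL else as.integer(unlist(ini$d)),
    s0 = ini$s %||% 0L,
    per0 = if (is.null(ini$per)) NULL else ini$per
  )
  rep_v <- validate_spec(problem$network, problem$costs)
  if (nrow(rep_v)) {
    stop("invalid model file:\n", paste0("  /", rep_v$component, "/", rep_v$field,
                                         ": ", rep_v$message, collapse = "\n"),
         call. = FALSE)
  }
  problem
}

#' Write a control problem to a model file
#'
#' The inverse of [read_model()]; `read_model(write_model(p, f))` restores
#' the problem, including the exact decimal representation of every
#' probability and cost.
#'
#' @param problem A [control_problem()].
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @return Invisibly, `path`.
#' @export
write_model <- function(problem, path) {
  net <- problem$network
  costs <- problem$costs
  obj <- list(
    genes = as.list(net$genes),
    controls = as.list(net$controls),
    nodes = lapply(net$nodes, function(nd) {
      lapply(seq_along(nd$exprs), function(j) {
        list(expr = nd$expr_text[j], prob = nd$prob_str[j])
      })
    }),
    q = net$q_str,
    p = net$p_str,
    costs = list(
      control = if (nrow(costs$control)) lapply(seq_len(nrow(costs$control)), function(i) {
        e <- list(u = costs$control$u[i], cost = costs$control$cost_str[i])
        if (!is.na(costs$control$x[i])) e$x <- costs$control$x[i]
        e
      }) else list(),
      terminal = if (nrow(costs$terminal)) lapply(seq_len(nrow(costs$terminal)), function(i) {
        list(state = costs$terminal$x[i], cost = costs$terminal$cost_str[i])
      }) else list(),
      default = costs$default_str
    ),
    horizon = costs$horizon,
    initial = list(
      x = bits_to_string(problem$x0),
      d = as.list(as.integer(problem$d0)),
      s = problem$s0,
      per = bits_to_string(problem$per0)
    )
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    stop("unsupported model-file extension (use .yaml or .json): ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write / read a policy table
#'
#' Policies are exchanged as TSV with columns `t`, `state_decimal`,
#' `state_binary`, `d`, `s`, `per`, (`u` under input timing) and `action`,
#' plus header comment lines recording timing and semantics.
#'
#' @param policy A policy tibble (from a `pbn_solution`).
#' @param path Destination TSV path.
#' @return Invisibly, `path`.
#' @export
write_policy <- function(policy, path) {
  timing <- attr(policy, "timing") %||% "direct"
  semantics <- attr(policy, "semantics") %||% "delayed"
  u0 <- attr(policy, "u0")
  df <- tibble::tibble(
    t = policy$t,
    state_decimal = policy$x_decimal,
    state_binary = policy$x,
    d = policy$d, s = policy$s, per = policy$per
  )
  if (timing == "input") df$u <- policy$u
  df$action <- policy$action
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# timing=%s semantics=%s%s", timing, semantics,
                     if (is.null(u0)) "" else sprintf(" u0=%d", u0)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_policy
#' @param path Path of a TSV written by [write_policy()].
#' @export
read_policy <- function(path) {
  header <- readLines(path, n = 1L)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character")
  pol <- tibble::tibble(
    t = as.integer(df$t),
    x = df$state_binary,
    x_decimal = as.numeric(df$state_decimal),
    d = df$d, s = as.integer(df$s), per = df$per,
    action = df$action
  )
  if ("u" %in% names(df)) pol$u <- df$u
  attr(pol, "timing") <- sub(".*timing=(\\S+).*", "\\1", header)
  attr(pol, "semantics") <- sub(".*semantics=(\\S+).*", "\\1", header)
  if (grepl("u0=", header)) attr(pol, "u0") <- as.integer(sub(".*u0=(\\d+).*", "\\1", header))
  class(pol) <- c("pbn_policy", class(pol))
  pol
}
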