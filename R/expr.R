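# Boolean predictor expressions.
#
# Candidate update functions f_j^(i) of a CS-PBNp are Boolean expressions
# over the gene variables and the control inputs, written with the model
# checker's operator spelling so that their arithmetized form can be pasted
# into generated code unchanged:
#
#   expr   := term ('|' term)*
#   term   := factor ('&' factor)*
#   factor := '!' factor | '(' expr ')' | var | '0' | '1'

expr_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "pbn_expr")
}

#' Parse a Boolean predictor expression
#'
#' Parses an expression over the gene and control variables of a network
#' into an abstract syntax tree.  Operators are `!` (not), `&` (and) and
#' `|` (or), with the usual precedence (`!` > `&` > `|`) and parentheses;
#' the constants `0` and `1` are allowed.
#'
#' @param text Expression string, e.g. `"x1 | u"` or `"x1 & !u"`.
#' @param network A [pbn_network()] (or any list with `genes` and `controls`
#'   character fields) providing the variable context.
#' @return An object of class `pbn_expr`.  [format()] renders the canonical
#'   form, and `parse_expr(format(e), network)` reproduces `e`.
#' @examples
#' net <- example_network()
#' e <- parse_expr("x1 & !u", net)
#' format(e)
#' eval_expr(e, x = c(1, 1), u = 1)
#' @seealso [eval_expr()], [arithmetize()]
#' @export
parse_expr <- function(text, network) {
  toks <- expr_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  e <- parse_or(st, network, text)
  if (st$pos <= nrow(st$toks)) {
    bad <- st$toks[st$pos, ]
    stop(sprintf("syntax error at position %d: unexpected '%s' in \"%s\"",
                 bad$at, bad$text, text), call. = FALSE)
  }
  e
}

expr_tokens <- function(text) {
  pat <- "([A-Za-z_][A-Za-z0-9_]*|[01()!&|])"
  out <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr(paste0("^", pat), substr(text, i, n)))
    if (length(m) == 0L) {
      stop(sprintf("syntax error at position %d: unexpected character '%s' in \"%s\"",
                   i, ch, text), call. = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(at = i, text = m, stringsAsFactors = FALSE)
    i <- i + nchar(m)
  }
  if (length(out) == 0L) stop("empty expression", call. = FALSE)
  do.call(rbind, out)
}

tok_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks[st$pos, "text"] else NA_character_

tok_take <- function(st) {
  t <- st$toks[st$pos, ]
  st$pos <- st$pos + 1L
  t
}

parse_or <- function(st, network, text) {
  e <- parse_and(st, network, text)
  while (identical(tok_peek(st), "|")) {
    tok_take(st)
    e <- expr_node("or", lhs = e, rhs = parse_and(st, network, text))
  }
  e
}

parse_and <- function(st, network, text) {
  e <- parse_factor(st, network, text)
  while (identical(tok_peek(st), "&")) {
    tok_take(st)
    e <- expr_node("and", lhs = e, rhs = parse_factor(st, network, text))
  }
  e
}

parse_factor <- function(st, network, text) {
  if (st$pos > nrow(st$toks)) {
    stop(sprintf("syntax error: unexpected end of expression in \"%s\"", text),
         call. = FALSE)
  }
  t <- tok_take(st)
  if (t$text == "!") {
    return(expr_node("not", operand = parse_factor(st, network, text)))
  }
  if (t$text == "(") {
    e <- parse_or(st, network, text)
    if (!identical(tok_peek(st), ")")) {
      stop(sprintf("syntax error at position %d: expected ')' in \"%s\"", t$at, text),
           call. = FALSE)
    }
    tok_take(st)
    return(e)
  }
  if (t$text %in% c("0", "1")) {
    return(expr_node("const", value = as.integer(t$text)))
  }
  gi <- match(t$text, network$genes)
  if (!is.na(gi)) {
    return(expr_node("var", name = t$text, type = "gene", index = gi))
  }
  ci <- match(t$text, network$controls)
  if (!is.na(ci)) {
    return(expr_node("var", name = t$text, type = "control", index = ci))
  }
  stop(sprintf("unknown variable '%s' at position %d in \"%s\"", t$text, t$at, text),
       call. = FALSE)
}

expr_level <- function(e) {
  switch(e$kind, or = 1L, and = 2L, 3L)
}

#' @export
format.pbn_expr <- function(x, ...) {
  wrap <- function(e, need) {
    s <- format(e)
    if (expr_level(e) < need) paste0("(", s, ")") else s
  }
  switch(x$kind,
    var = x$name,
    const = as.character(x$value),
    not = paste0("!", wrap(x$operand, 3L)),
    and = paste0(wrap(x$lhs, 2L), " & ", wrap(x$rhs, 2L)),
    or = paste0(wrap(x$lhs, 1L), " | ", wrap(x$rhs, 1L))
  )
}

#' @export
print.pbn_expr <- function(x, ...) {
  cat("<pbn_expr> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a Boolean predictor expression
#'
#' @param expr A `pbn_expr` from [parse_expr()].
#' @param x Integer 0/1 vector of gene values (position i is gene i).
#' @param u Integer 0/1 vector of control values (may be omitted when the
#'   expression has no control variables).
#' @return `0L` or `1L`.
#' @examples
#' net <- example_network()
#' eval_expr(parse_expr("x1 | u", net), x = c(1, 0), u = 0)
#' @export
eval_expr <- function(expr, x, u = integer()) {
  v <- eval_expr_vec(expr, matrix(as.integer(x), nrow = 1),
                     matrix(as.integer(u), nrow = 1))
  v[1]
}

# vectorized evaluation over rows of assignment matrices
eval_expr_vec <- function(expr, xm, um) {
  switch(expr$kind,
    const = rep(expr$value, nrow(xm)),
    var = if (expr$type == "gene") xm[, expr$index] else um[, expr$index],
    not = 1L - eval_expr_vec(expr$operand, xm, um),
    and = eval_expr_vec(expr$lhs, xm, um) * eval_expr_vec(expr$rhs, xm, um),
    or = {
      a <- eval_expr_vec(expr$lhs, xm, um)
      b <- eval_expr_vec(expr$rhs, xm, um)
      pmin(a + b, 1L)
    }
  )
}

# variable references of an expression
expr_vars <- function(expr) {
  switch(expr$kind,
    const = character(),
    var = stats::setNames(expr$name, expr$type),
    not = expr_vars(expr$operand),
    unique(c(expr_vars(expr$lhs), expr_vars(expr$rhs)))
  )
}

#' Arithmetize a Boolean expression
#'
#' Rewrites a Boolean expression as a polynomial over the same variables
#' that agrees with it on every 0/1 assignment, using the identities
#' `!x ~ 1-x`, `x|y ~ x+y-x*y`, `x&y ~ x*y`.  The returned string is used
#' verbatim in generated model-checker `formula` lines.
#'
#' @param expr A `pbn_expr`.
#' @return A character scalar, e.g. `"x1+u-x1*u"` for `x1 | u`.
#' @examples
#' net <- example_network()
#' arithmetize(parse_expr("x1 | u", net))
#' arithmetize(parse_expr("!x1", net))
#' @export
arithmetize <- function(expr) {
  arith_node(expr)$str
}

arith_node <- function(e) {
  # lvl: 3 atom, 2 product, 1 sum
  wrap <- function(a) if (a$lvl <= 1L) paste0("(", a$str, ")") else a$str
  switch(e$kind,
    var = list(str = e$name, lvl = 3L),
    const = list(str = as.character(e$value), lvl = 3L),
    not = {
      a <- arith_node(e$operand)
      list(str = paste0("1-", wrap(a)), lvl = 1L)
    },
    and = {
      a <- arith_node(e$lhs)
      b <- arith_node(e$rhs)
      list(str = paste0(wrap(a), "*", wrap(b)), lvl = 2L)
    },
    or = {
      a <- arith_node(e$lhs)
      b <- arith_node(e$rhs)
      list(str = paste0(a$str, "+", b$str, "-", wrap(a), "*", wrap(b)), lvl = 1L)
    }
  )
}

# Truth table of an expression over all assignments, ordered with the
# gene code major (MSB = x1) and the control code minor (MSB = u1):
# entry index = x_code * 2^m + u_code + 1.
expr_table <- function(expr, n, m) {
  xg <- bit_grid(n)
  ug <- bit_grid(m)
  xm <- xg[rep(seq_len(nrow(xg)), each = nrow(ug)), , drop = FALSE]
  um <- ug[rep(seq_len(nrow(ug)), times = nrow(xg)), , drop = FALSE]
  as.integer(eval_expr_vec(expr, xm, um))
}

# rows = codes 0..2^k-1 in order, columns bit 1..k with MSB = bit 1
bit_grid <- function(k) {
  if (k == 0L) return(matrix(integer(), nrow = 1, ncol = 0))
  codes <- 0:(2^k - 1)
  m <- sapply(seq_len(k), function(i) bitwAnd(codes %/% 2^(k - i), 1L))
  matrix(as.integer(m), ncol = k)
}

bits_to_code <- function(bits) {
  if (length(bits) == 0L) return(0L)
  sum(bits * 2^(rev(seq_along(bits)) - 1L))
}

code_to_bits <- function(code, k) {
  if (k == 0L) return(integer())
  vapply(seq_len(k), function(i) bitwAnd(code %/% 2^(k - i), 1L), integer(1))
}

bits_to_string <- function(bits) paste(bits, collapse = "")

string_to_bits <- function(s) {
  if (!grepl("^[01]+$", s)) stop("expected a binary string, got '", s, "'", call. = FALSE)
  as.integer(strsplit(s, "")[[1]])
}
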