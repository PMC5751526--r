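# Exact fixed-point decimal arithmetic.
#
# Every probability and cost in a CS-PBNp model file is a terminating
# decimal, and products and sums of terminating decimals terminate, so the
# whole backward induction can be carried out exactly in the form
# mantissa / 10^exp with an arbitrary-length integer mantissa.  The mantissa
# is stored little-endian in base 1e7 inside a double vector: limb products
# stay below 2^53, no external big-integer library is required, and no gcd
# reduction is ever needed because denominators are always powers of ten.

DEC_BASE <- 1e7

big_trim <- function(limbs) {
  n <- length(limbs)
  while (n > 1L && limbs[n] == 0) n <- n - 1L
  limbs[seq_len(n)]
}

big_carry <- function(limbs) {
  i <- 1L
  while (i <= length(limbs)) {
    ci <- limbs[i] %/% DEC_BASE
    if (ci != 0) {
      limbs[i] <- limbs[i] - ci * DEC_BASE
      if (i == length(limbs)) limbs <- c(limbs, 0)
      limbs[i + 1L] <- limbs[i + 1L] + ci
    }
    i <- i + 1L
  }
  big_trim(limbs)
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_carry(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

# assumes a >= b
big_sub <- function(a, b) {
  n <- max(length(a), length(b))
  r <- c(a, rep(0, n - length(a))) - c(b, rep(0, n - length(b)))
  for (i in seq_len(n - 1L)) {
    if (r[i] < 0) {
      r[i] <- r[i] + DEC_BASE
      r[i + 1L] <- r[i + 1L] - 1
    }
  }
  if (r[n] < 0) stop("big_sub: negative result")
  big_trim(r)
}

big_mul <- function(a, b) {
  r <- rep(0, length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    seg <- seq_along(b) + i - 1L
    r[seg] <- r[seg] + a[i] * b
    # keep partial sums well below 2^53
    carry <- r %/% DEC_BASE
    if (any(carry > 0)) {
      r <- r - carry * DEC_BASE
      r[seq_along(carry)[-1]] <- r[seq_along(carry)[-1]] + carry[-length(carry)]
      if (carry[length(carry)] > 0) r <- c(r, carry[length(carry)])
    }
  }
  big_carry(r)
}

big_mul_small <- function(a, m) big_carry(a * m)

big_cmp <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

big_is_zero <- function(a) length(big_trim(a)) == 1L && big_trim(a)[1] == 0

# multiply mantissa by 10^k
big_shift10 <- function(a, k) {
  while (k >= 7L) {
    a <- big_mul_small(a, 1e7)
    k <- k - 7L
  }
  if (k > 0L) a <- big_mul_small(a, 10^k)
  a
}

new_dec <- function(limbs, exp) {
  structure(list(limbs = big_trim(limbs), exp = as.integer(exp)),
            class = "pbn_dec")
}

dec_zero <- function() new_dec(0, 0L)
dec_one <- function() new_dec(1, 0L)

is_dec <- function(x) inherits(x, "pbn_dec")

#' @export
print.pbn_dec <- function(x, ...) {
  cat("<exact decimal> ", dec_format(x), "\n", sep = "")
  invisible(x)
}

dec_parse <- function(s) {
  s <- trimws(s)
  if (!grepl("^[0-9]+(\\.[0-9]*)?$", s)) {
    stop("not a nonnegative decimal literal: '", s, "'", call. = FALSE)
  }
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  frac <- if (length(parts) == 2L) parts[2] else ""
  digits <- paste0(parts[1], frac)
  digits <- sub("^0+(?=.)", "", digits, perl = TRUE)
  # pack decimal digits into base-1e7 limbs, little-endian
  nd <- nchar(digits)
  starts <- seq(nd, 1, by = -7L)
  limbs <- vapply(starts, function(e) {
    b <- max(1L, e - 6L)
    as.numeric(substr(digits, b, e))
  }, numeric(1))
  dec_canonical(new_dec(limbs, nchar(frac)))
}

# strip trailing decimal zeros so exp is minimal
dec_canonical <- function(d) {
  if (big_is_zero(d$limbs)) return(new_dec(0, 0L))
  while (d$exp > 0L) {
    q <- big_divmod10(d$limbs)
    if (q$rem != 0) break
    d <- new_dec(q$quot, d$exp - 1L)
  }
  d
}

big_divmod10 <- function(a) {
  quot <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * DEC_BASE + a[i]
    quot[i] <- cur %/% 10
    rem <- cur %% 10
  }
  list(quot = big_trim(quot), rem = rem)
}

dec_align <- function(a, b) {
  if (a$exp == b$exp) return(list(a = a$limbs, b = b$limbs, exp = a$exp))
  if (a$exp < b$exp) {
    list(a = big_shift10(a$limbs, b$exp - a$exp), b = b$limbs, exp = b$exp)
  } else {
    list(a = a$limbs, b = big_shift10(b$limbs, a$exp - b$exp), exp = a$exp)
  }
}

dec_add <- function(a, b) {
  al <- dec_align(a, b)
  new_dec(big_add(al$a, al$b), al$exp)
}

dec_sub <- function(a, b) {
  al <- dec_align(a, b)
  dec_canonical(new_dec(big_sub(al$a, al$b), al$exp))
}

dec_mul <- function(a, b) {
  if (big_is_zero(a$limbs) || big_is_zero(b$limbs)) return(dec_zero())
  new_dec(big_mul(a$limbs, b$limbs), a$exp + b$exp)
}

dec_cmp <- function(a, b) {
  al <- dec_align(a, b)
  big_cmp(al$a, al$b)
}

dec_sum <- function(xs) Reduce(dec_add, xs, dec_zero())

dec_prod <- function(xs) Reduce(dec_mul, xs, dec_one())

dec_one_minus <- function(d) dec_sub(dec_one(), d)

dec_is_zero <- function(d) big_is_zero(d$limbs)

dec_to_num <- function(d) {
  v <- sum(d$limbs * DEC_BASE^(seq_along(d$limbs) - 1L))
  v / 10^d$exp
}

dec_format <- function(d) {
  d <- dec_canonical(d)
  digits <- paste0(
    sub("^0+(?=.)", "", sprintf("%07.0f", d$limbs[length(d$limbs)]), perl = TRUE),
    paste(rev(sprintf("%07.0f", d$limbs[-length(d$limbs)])), collapse = "")
  )
  if (d$exp == 0L) return(digits)
  if (nchar(digits) <= d$exp) {
    digits <- paste0(strrep("0", d$exp - nchar(digits) + 1L), digits)
  }
  paste0(
    substr(digits, 1L, nchar(digits) - d$exp), ".",
    substr(digits, nchar(digits) - d$exp + 1L, nchar(digits))
  )
}

# Canonical conversion used everywhere a model quantity enters the package:
# numerics are rendered at 15 significant digits (so 0.3 stays "0.3"),
# characters must be decimal literals, exact decimals pass through.
as_dec <- function(x) {
  if (is_dec(x)) return(x)
  if (is.character(x)) return(dec_parse(x))
  if (is.numeric(x)) {
    if (is.na(x) || x < 0) stop("expected a nonnegative number", call. = FALSE)
    return(dec_parse(format(x, digits = 15, scientific = FALSE)))
  }
  stop("cannot interpret as exact decimal", call. = FALSE)
}

dec_str <- function(x) dec_format(as_dec(x))
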