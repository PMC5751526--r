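# Full dynamic state of a CS-PBNp: gene values x, context d (selected
# function index per gene), pending switch indicator s and pending
# perturbation indicators per.  States are indexed 1..2^n * prod(l) * 2 * 2^n
# with x lexicographically major (MSB = x1), then d, then s, then per.

state_space_size <- function(network) {
  n <- n_genes(network)
  2^n * prod(n_funs(network)) * 2 * 2^n
}

# d (1-based per gene) <-> 0-based mixed-radix code, d1 most significant
d_to_code <- function(d, l) {
  code <- 0L
  for (i in seq_along(l)) code <- code * l[i] + (d[i] - 1L)
  code
}

code_to_d <- function(code, l) {
  d <- integer(length(l))
  for (i in rev(seq_along(l))) {
    d[i] <- code %% l[i] + 1L
    code <- code %/% l[i]
  }
  d
}

encode_state <- function(network, x, d, s, per) {
  n <- n_genes(network)
  l <- n_funs(network)
  idx <- bits_to_code(x)
  idx <- idx * prod(l) + d_to_code(d, l)
  idx <- idx * 2L + s
  idx <- idx * 2^n + bits_to_code(per)
  idx + 1L
}

decode_state <- function(network, idx) {
  n <- n_genes(network)
  l <- n_funs(network)
  code <- idx - 1L
  per <- code_to_bits(code %% 2^n, n); code <- code %/% 2^n
  s <- code %% 2L; code <- code %/% 2L
  d <- code_to_d(code %% prod(l), l); code <- code %/% prod(l)
  x <- code_to_bits(code, n)
  list(x = x, d = d, s = as.integer(s), per = per)
}

as_state <- function(network, state) {
  if (is.numeric(state) && length(state) == 1L) return(decode_state(network, state))
  x <- if (is.character(state$x)) string_to_bits(state$x) else as.integer(state$x)
  d <- as.integer(state$d)
  per <- if (is.character(state$per)) string_to_bits(state$per) else as.integer(state$per)
  list(x = x, d = d, s = as.integer(state$s), per = per)
}

state_row <- function(st) {
  tibble::tibble(
    x = bits_to_string(st$x),
    d = paste(st$d, collapse = ","),
    s = st$s,
    per = bits_to_string(st$per)
  )
}

#' Enumerate the full dynamic state space
#'
#' Lists every model state (gene vector, context, switch indicator,
#' perturbation indicators) exactly once, in a stable order: gene state
#' lexicographic with MSB = x1, then context, then switch, then
#' perturbation bits.
#'
#' @param network A [pbn_network()].
#' @return A tibble with columns `state` (index), `x`, `d`, `s`, `per` and
#'   `x_decimal` (decimal encoding of the gene state, MSB = x1).
#' @examples
#' nrow(enumerate_states(example_network()))  # 2^2 * 4 * 2 * 2^2 = 128
#' @export
enumerate_states <- function(network) {
  N <- state_space_size(network)
  rows <- lapply(seq_len(N), function(i) {
    st <- decode_state(network, i)
    cbind(state = i, state_row(st), x_decimal = bits_to_code(st$x))
  })
  dplyr::bind_rows(rows)
}
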