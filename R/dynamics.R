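# The exact one-step stochastic kernel of a CS-PBNp under a chosen control.
#
# Reference ("delayed") semantics, mirroring the synchronous module
# encoding: the switch and perturbation indicators carried in the current
# state decide this step's behaviour, while fresh indicators for the next
# step are sampled alongside.  For each gene i,
#   x'_i = 1 - x_i                if per_i = 1,
#   x'_i = f_{d'_i}(x, u)         otherwise,
# where d'_i is resampled from c^(i) when s = 1 (for every gene, perturbed
# or not) and retained otherwise; independently s' ~ Bernoulli(q) and
# per'_i ~ Bernoulli(p).
#
# The "immediate" alternative samples switch and perturbation within the
# transition and applies them at once; the stored indicators then record
# what was just applied.
#
# Probabilities are assembled as exact decimals (factors multiplied in the
# fixed order: switch, perturbation bits, function choices) and converted
# to doubles once, so the kernel is bit-stable and identical to what the
# generated model-checker code denotes.  Branch probabilities do not
# depend on the source state (only on whether the context resamples), so
# they are tabulated once per network.

# Precomputed evaluation contexts are memoized per network fingerprint so
# that repeated one-off calls (sample_step in particular) stay cheap.
.kernel_contexts <- new.env(parent = emptyenv())

# Precomputed evaluation context for a network.
kernel_context <- function(network, semantics = c("delayed", "immediate")) {
  semantics <- match.arg(semantics)
  fp <- paste(semantics, network$q_str, network$p_str,
              paste(network$genes, collapse = ","),
              paste(network$controls, collapse = ","),
              paste(unlist(lapply(network$nodes, function(nd) {
                c(nd$expr_text, nd$prob_str)
              })), collapse = "|"),
              sep = ";")
  hit <- .kernel_contexts[[fp]]
  if (!is.null(hit)) return(hit)
  ctx <- kernel_context_build(network, semantics)
  .kernel_contexts[[fp]] <- ctx
  ctx
}

kernel_context_build <- function(network, semantics) {
  n <- n_genes(network)
  m <- n_controls(network)
  l <- n_funs(network)
  ftab <- lapply(seq_len(n), function(i) {
    lapply(network$nodes[[i]]$exprs, expr_table, n = n, m = m)
  })
  q_dec <- dec_parse(network$q_str)
  p_dec <- dec_parse(network$p_str)
  s_branch <- list(list(v = 1L, dec = q_dec), list(v = 0L, dec = dec_one_minus(q_dec)))
  per_branch <- list(list(v = 1L, dec = p_dec), list(v = 0L, dec = dec_one_minus(p_dec)))
  c_dec <- lapply(network$nodes, function(nd) lapply(nd$prob_str, dec_parse))

  # enumerate branches in module order (switch, perturbation bits, function
  # choices) once, for the retain and the resample case
  enum_branches <- function(resample) {
    d_assigns <- if (resample) {
      combos <- list(list(d = integer(0), dec = list()))
      for (i in seq_len(n)) {
        combos <- unlist(lapply(combos, function(co) {
          lapply(seq_len(l[i]), function(j) {
            list(d = c(co$d, j), dec = c(co$dec, list(c_dec[[i]][[j]])))
          })
        }), recursive = FALSE)
      }
      combos
    } else {
      list(list(d = NULL, dec = list()))
    }
    out <- list()
    for (sb in s_branch) {
      for (pc in 0:(2^n - 1)) {
        # per1 = 1 branch first, matching the module command order
        per_new <- 1L - code_to_bits(pc, n)
        per_dec <- lapply(seq_len(n), function(i) {
          if (per_new[i] == 1L) per_branch[[1]]$dec else per_branch[[2]]$dec
        })
        for (co in d_assigns) {
          dec <- dec_prod(c(list(sb$dec), per_dec, co$dec))
          out[[length(out) + 1L]] <- list(
            s = sb$v, per = per_new, per_code = bits_to_code(per_new),
            d = co$d, dec = dec, prob = dec_to_num(dec)
          )
        }
      }
    }
    keep <- !vapply(out, function(b) b$prob == 0, logical(1))
    out[keep]
  }
  list(
    network = network, semantics = semantics, n = n, m = m, l = l,
    ftab = ftab,
    branches = list(retain = enum_branches(FALSE), resample = enum_branches(TRUE)),
    cache = new.env(parent = emptyenv())
  )
}

# Successors of one state under control code u_code.
# Returns list(idx, prob, dec); successors are distinct under the delayed
# semantics; collisions (possible under immediate semantics) are merged by
# exact addition.
kernel_succ <- function(ctx, idx, u_code) {
  key <- paste0(idx, "_", u_code)
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  st <- decode_state(ctx$network, idx)
  n <- ctx$n
  l <- ctx$l
  xu <- bits_to_code(st$x) * 2^ctx$m + u_code + 1L
  fx <- vapply(seq_len(n), function(i) {
    vapply(seq_len(l[i]), function(j) ctx$ftab[[i]][[j]][xu], integer(1))[seq_len(max(l))]
  }, integer(max(l)))
  # fx[j, i] = f_j^(i)(x, u), recycled rows beyond l[i] unused
  delayed <- ctx$semantics == "delayed"
  branches <- if (delayed) {
    if (st$s == 1L) ctx$branches$resample else ctx$branches$retain
  } else NULL

  # mixed-radix offsets for direct successor-index arithmetic
  D <- prod(l)
  per_base <- 2^n
  s_stride <- per_base
  d_stride <- 2L * per_base
  x_stride <- D * d_stride

  succ_of <- function(b, use_per_now) {
    dn <- if (is.null(b$d)) st$d else b$d
    per_eff <- if (use_per_now) b$per else st$per
    xn <- integer(n)
    for (i in seq_len(n)) {
      xn[i] <- if (per_eff[i] == 1L) 1L - st$x[i] else fx[dn[i], i]
    }
    bits_to_code(xn) * x_stride + d_to_code(dn, l) * d_stride +
      b$s * s_stride + b$per_code + 1L
  }

  if (delayed) {
    out_idx <- vapply(branches, succ_of, numeric(1), use_per_now = FALSE)
    out_dec <- lapply(branches, `[[`, "dec")
    out_prob <- vapply(branches, `[[`, "prob", FUN.VALUE = numeric(1))
  } else {
    # immediate: the resample decision follows the freshly sampled switch
    br_r <- ctx$branches$resample
    br_k <- ctx$branches$retain
    use_r <- vapply(br_r, function(b) b$s == 1L, logical(1))
    use_k <- vapply(br_k, function(b) b$s == 0L, logical(1))
    branches <- c(br_r[use_r], br_k[use_k])
    out_idx <- vapply(branches, succ_of, numeric(1), use_per_now = TRUE)
    out_dec <- lapply(branches, `[[`, "dec")
    out_prob <- vapply(branches, `[[`, "prob", FUN.VALUE = numeric(1))
  }

  o <- order(out_idx)
  idx_s <- out_idx[o]
  if (anyDuplicated(idx_s)) {
    dec_s <- out_dec[o]
    agg_idx <- numeric(0)
    agg_dec <- list()
    for (k in seq_along(idx_s)) {
      if (length(agg_idx) && agg_idx[length(agg_idx)] == idx_s[k]) {
        agg_dec[[length(agg_dec)]] <- dec_add(agg_dec[[length(agg_dec)]], dec_s[[k]])
      } else {
        agg_idx <- c(agg_idx, idx_s[k])
        agg_dec[[length(agg_dec) + 1L]] <- dec_s[[k]]
      }
    }
    res <- list(idx = agg_idx, dec = agg_dec,
                prob = vapply(agg_dec, dec_to_num, numeric(1)))
  } else {
    res <- list(idx = idx_s, dec = out_dec[o], prob = out_prob[o])
  }
  ctx$cache[[key]] <- res
  res
}

#' One-step transition distribution
#'
#' The exact distribution over successor model states from a given state
#' under a chosen control vector.
#'
#' @param network A [pbn_network()].
#' @param state A state: either an index from [enumerate_states()] or a
#'   list with elements `x`, `d`, `s`, `per` (binary strings or vectors).
#' @param u Control vector: binary string, 0/1 vector, or a single integer
#'   0/1 when there is one control input.
#' @param semantics `"delayed"` (reference: the stored switch/perturbation
#'   indicators act this step, fresh ones are sampled for the next) or
#'   `"immediate"` (sampled and applied within the transition).
#' @param exact If `TRUE`, adds a column `prob_exact` with the exact
#'   decimal probability strings.
#' @return A tibble with columns `state`, `x`, `d`, `s`, `per`, `prob`
#'   (and optionally `prob_exact`), probabilities summing to one.
#' @examples
#' net <- example_network()
#' step_distribution(net, list(x = "11", d = c(1, 1), s = 0, per = "00"), u = 0)
#' @export
step_distribution <- function(network, state, u,
                              semantics = c("delayed", "immediate"),
                              exact = FALSE) {
  semantics <- match.arg(semantics)
  ctx <- kernel_context(network, semantics)
  st <- as_state(network, state)
  check_state(network, st)
  u_bits <- as_control(network, u)
  succ <- kernel_succ(ctx, encode_state(network, st$x, st$d, st$s, st$per),
                      bits_to_code(u_bits))
  rows <- dplyr::bind_rows(lapply(seq_along(succ$idx), function(k) {
    cbind(state = succ$idx[k], state_row(decode_state(network, succ$idx[k])))
  }))
  rows$prob <- succ$prob
  if (exact) rows$prob_exact <- vapply(succ$dec, dec_format, character(1))
  tibble::as_tibble(rows)
}

check_state <- function(network, st) {
  n <- n_genes(network)
  l <- n_funs(network)
  if (length(st$x) != n || !all(st$x %in% 0:1) ||
      length(st$d) != n || any(st$d < 1L | st$d > l) ||
      !st$s %in% 0:1 ||
      length(st$per) != n || !all(st$per %in% 0:1)) {
    stop("invalid model state for this network", call. = FALSE)
  }
  invisible(st)
}

as_control <- function(network, u) {
  m <- n_controls(network)
  u_bits <- if (is.character(u)) string_to_bits(u) else as.integer(u)
  if (m == 0L && length(u_bits) == 0L) return(integer())
  if (length(u_bits) != m || !all(u_bits %in% 0:1)) {
    stop(sprintf("control must be a %d-bit 0/1 vector", m), call. = FALSE)
  }
  u_bits
}

#' Marginal gene-state distribution of a transition distribution
#'
#' Aggregates a [step_distribution()] tibble over context, switch and
#' perturbation components, leaving the distribution of the gene vector.
#'
#' @param dist A tibble as returned by [step_distribution()].
#' @return A tibble with columns `x` and `prob` summing to one.
#' @export
x_marginal <- function(dist) {
  dist |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(prob = sum(.data$prob), .groups = "drop") |>
    dplyr::arrange(.data$x)
}

#' Sample one transition
#'
#' Draws a successor state from the one-step kernel.  Uses R's global RNG;
#' seed with [set.seed()] or [withr::with_seed()] for reproducibility.
#'
#' @inheritParams step_distribution
#' @return A one-row tibble with columns `state`, `x`, `d`, `s`, `per`.
#' @export
sample_step <- function(network, state, u, semantics = c("delayed", "immediate")) {
  semantics <- match.arg(semantics)
  d <- step_distribution(network, state, u, semantics)
  k <- sample.int(nrow(d), 1L, prob = d$prob)
  d[k, c("state", "x", "d", "s", "per")]
}
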