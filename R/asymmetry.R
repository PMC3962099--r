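# C190 asymmetry statistic and residue-pair propensities.

#' C190 asymmetry between a dipeptide and its antidipeptide
#'
#' The asymmetry between the counts of a dipeptide AB and its mirror-image
#' antidipeptide BA:
#' \deqn{C_{190} = 100 \cdot \frac{|n_{AB} - n_{BA}|}{(n_{AB} + n_{BA})/2}}
#' The x100 scale matches the published convention for this statistic
#' (equal counts give 0; one count zero gives the maximum, 200). The value
#' is undefined (`NA`) when both counts are zero. Vectorized.
#'
#' @param n_ab,n_ba Counts of the two orientations (non-negative; real
#'   values are accepted so the same formula serves analytic expectations).
#' @return Numeric, in `[0, 200]`, `NA` where both counts are 0.
#' @examples
#' c190(5384, 7571) # 33.76...
#' @export
c190 <- function(n_ab, n_ba) {
  abs(signed_c190(n_ab, n_ba))
}

#' Signed C190
#'
#' Same magnitude as [c190()] but keeping the sign of `n_ab - n_ba`, so a
#' positive value means the AB orientation dominates. Antisymmetric under
#' swapping its arguments. By package convention signed values are reported
#' with A the alphabetically first residue of the pair.
#'
#' @inheritParams c190
#' @return Numeric in `[-200, 200]`, `NA` where both counts are 0.
#' @export
signed_c190 <- function(n_ab, n_ba) {
  stopifnot(is.numeric(n_ab), is.numeric(n_ba))
  if (any(n_ab < 0, na.rm = TRUE) || any(n_ba < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  tot <- n_ab + n_ba
  ifelse(tot > 0, 100 * (n_ab - n_ba) / (tot / 2), NA_real_)
}

#' Asymmetry table: C190 for all 190 unordered residue pairs
#'
#' Computes, for each of the 190 unordered pairs of distinct standard
#' residues (same-residue dipeptides are ignored by construction), the
#' counts in both orientations and the absolute and signed C190. Pairs with
#' zero counts in both orientations are flagged undefined and carry `NA`.
#'
#' @param counts A `"dipeptide_counts"` matrix from [count_pairs()].
#' @return A data frame of class `"asymmetry_table"` with 190 rows and
#'   columns `pair` (canonical label, alphabetical orientation), `first`,
#'   `second`, `n_ab`, `n_ba`, `c190`, `signed_c190`, `defined`. The signed
#'   value is oriented so `n_ab` is the count of the alphabetically first
#'   residue preceding the second.
#' @export
asymmetry_table <- function(counts) {
  counts <- .as_count_matrix(counts)
  idx <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)  # row < col
  a <- .AA20[idx[, 1L]]
  b <- .AA20[idx[, 2L]]
  n_ab <- counts[idx]
  n_ba <- counts[idx[, c(2L, 1L)]]
  s <- signed_c190(n_ab, n_ba)
  out <- data.frame(pair = paste0(a, b), first = a, second = b,
                    n_ab = n_ab, n_ba = n_ba,
                    c190 = abs(s), signed_c190 = s,
                    defined = (n_ab + n_ba) > 0,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pair), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "gap") <- attr(counts, "gap")
  class(out) <- c("asymmetry_table", "data.frame")
  out
}

#' Propensity of an ordered residue pair
#'
#' The propensity of residue B to precede residue J,
#' \deqn{P(BJ) = \frac{n_{BJ}/n_{XJ}}{n_{BX}/n_{XX}}}
#' i.e. the observed frequency of B in front of J relative to what B's
#' overall first-position frequency predicts under independence. 1 means no
#' preference. Undefined (`NA`) when a needed marginal is zero.
#'
#' @param counts A `"dipeptide_counts"` matrix.
#' @param first,second One-letter codes of the ordered pair (B then J).
#' @return A single propensity value.
#' @export
propensity <- function(counts, first, second) {
  counts <- .as_count_matrix(counts)
  stopifnot(first %in% .AA20, second %in% .AA20)
  m <- marginals(counts)
  n_xj <- m$n_second[[second]]
  n_bx <- m$n_first[[first]]
  if (m$n_total == 0 || n_xj == 0 || n_bx == 0) return(NA_real_)
  (counts[first, second] / n_xj) / (n_bx / m$n_total)
}

#' Propensity table for all 400 ordered pairs
#'
#' @param counts A `"dipeptide_counts"` matrix.
#' @return A data frame of class `"propensity_table"` with 400 rows:
#'   `first`, `second`, `n` (the pair count), `propensity`, `defined`.
#'   Entries whose marginals vanish are flagged undefined (`NA`), never
#'   silently zeroed.
#' @export
propensity_table <- function(counts) {
  counts <- .as_count_matrix(counts)
  n <- sum(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  p <- matrix(NA_real_, 20L, 20L, dimnames = dimnames(counts))
  if (n > 0) {
    ok <- outer(rs > 0, cs > 0, "&")
    num <- sweep(counts, 2L, ifelse(cs > 0, cs, 1), "/")
    den <- rs / n
    p[ok] <- sweep(num, 1L, ifelse(den > 0, den, 1), "/")[ok]
  }
  out <- data.frame(first = rep(.AA20, each = 20L),
                    second = rep(.AA20, times = 20L),
                    n = as.vector(t(counts)),
                    propensity = as.vector(t(p)),
                    stringsAsFactors = FALSE)
  out$defined <- !is.na(out$propensity)
  class(out) <- c("propensity_table", "data.frame")
  out
}

#' Absolute difference between a pair of propensities
#'
#' Convenience for comparing a dipeptide's propensity with its
#' antidipeptide's, as in ranked propensity-difference reports.
#'
#' @param p_ab,p_ba Propensity values.
#' @return `|p_ab - p_ba|`, vectorized.
#' @export
propensity_difference <- function(p_ab, p_ba) {
  abs(p_ab - p_ba)
}

#' Per-residue average C190
#'
#' For each residue X, the mean and standard error of the C190 values of
#' the 19 pairs that contain X. Undefined pairs are excluded and the
#' divisor reduced accordingly; the standard error uses the sample standard
#' deviation (n - 1 denominator) divided by sqrt(n). A residue with a
#' single defined pair reports SE 0; one with none is flagged undefined.
#'
#' @param at An `"asymmetry_table"` from [asymmetry_table()].
#' @return Data frame with columns `residue`, `n_pairs`, `mean_c190`,
#'   `std_error`.
#' @export
residue_averages <- function(at) {
  stopifnot(inherits(at, "asymmetry_table") || is.data.frame(at))
  vapply_res <- function(x) {
    v <- at$c190[(at$first == x | at$second == x) & at$defined]
    n <- length(v)
    c(n,
      if (n > 0) mean(v) else NA_real_,
      if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_)
  }
  m <- vapply(.AA20, vapply_res, numeric(3L))
  data.frame(residue = .AA20, n_pairs = as.integer(m[1L, ]),
             mean_c190 = m[2L, ], std_error = m[3L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top asymmetric pairs
#'
#' Ranks the defined entries of an asymmetry table by decreasing C190
#' (ties broken alphabetically by pair label) and returns the first
#' `top_k`.
#'
#' @param at An `"asymmetry_table"`.
#' @param top_k Number of pairs to return (>= 1).
#' @return The selected rows of `at`, highest asymmetry first.
#' @export
rank_pairs <- function(at, top_k = 7L) {
  top_k <- .check_count_scalar(top_k, "top_k", min = 1L)
  d <- at[at$defined, , drop = FALSE]
  d <- d[order(-d$c190, d$pair), , drop = FALSE]
  out <- utils::head(d, top_k)
  rownames(out) <- NULL
  out
}
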