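# Sampling-sufficiency analysis by non-overlapping subsampling (fragmented
# prediction performance plot, FPPP) and a sequence-level bootstrap for the
# C190 of selected pairs.

#' Partition a sequence set into non-overlapping subsets
#'
#' A seeded uniform random permutation of the set is cut into
#' `floor(N / subset_size)` consecutive chunks of exactly `subset_size`
#' sequences; leftovers are discarded. The same seed always yields the same
#' partition.
#'
#' @param seqs Named character vector of sequences.
#' @param subset_size Number of sequences per subset (1 <= size <= N).
#' @param seed Integer seed for the permutation.
#' @return A list of named character vectors (disjoint subsets).
#' @export
partition_sequences <- function(seqs, subset_size, seed = 1L) {
  n <- length(seqs)
  subset_size <- .check_count_scalar(subset_size, "subset_size", min = 1L)
  if (subset_size > n)
    stop("subset_size (", subset_size, ") exceeds the set size (", n, ")",
         call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  n_sub <- n %/% subset_size
  lapply(seq_len(n_sub), function(i) {
    seqs[perm[seq.int((i - 1L) * subset_size + 1L, i * subset_size)]]
  })
}

#' FPPP stability analysis of the C190 values
#'
#' For each requested subset size, the set is partitioned into
#' non-overlapping subsets ([partition_sequences()]), the 190 C190 values
#' are computed on every subset, and their per-pair mean and standard error
#' across subsets are reported. A flat mean across sizes (relative to its
#' SE) indicates the full set is large enough for stable C190 estimates.
#' A pair undefined in some subset is excluded from that subset's
#' contribution (divisor reduced); the SE uses the sample standard
#' deviation (n - 1) over subsets divided by sqrt(n), reported as 0 when
#' only one subset contributes.
#'
#' @param seqs Named character vector of sequences.
#' @param subset_sizes Integer vector of subset sizes (each <= N).
#' @param seed Integer seed; the partition for the i-th size uses
#'   `seed + i - 1`.
#' @param gap,skip_initial_met Passed to [count_pairs()].
#' @return A data frame with one row per (subset size, pair): columns
#'   `subset_size`, `n_subsets`, `pair`, `first`, `second`, `n_defined`,
#'   `mean_c190`, `std_error`; attributes `seed` and `gap`.
#' @export
fppp_analysis <- function(seqs, subset_sizes, seed = 1L, gap = 0L,
                          skip_initial_met = FALSE) {
  if (length(subset_sizes) == 0L)
    stop("`subset_sizes` must not be empty", call. = FALSE)
  res <- lapply(seq_along(subset_sizes), function(i) {
    size <- .check_count_scalar(subset_sizes[i], "subset_sizes", min = 1L)
    subsets <- partition_sequences(seqs, size, seed = seed + i - 1L)
    vals <- vapply(subsets, function(s) {
      asymmetry_table(count_pairs(s, gap = gap,
                                  skip_initial_met = skip_initial_met))$c190
    }, numeric(190L))
    vals <- matrix(vals, nrow = 190L)  # rows = pairs, cols = subsets
    n_def <- rowSums(!is.na(vals))
    mean_c <- ifelse(n_def > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
    se <- apply(vals, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
      else if (length(v) == 1L) 0 else NA_real_
    })
    pairs <- asymmetry_table(count_pairs(character(0L)))[, c("pair", "first", "second")]
    data.frame(subset_size = size, n_subsets = length(subsets), pairs,
               n_defined = n_def, mean_c190 = mean_c, std_error = se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "gap") <- gap
  out
}

# Per-sequence counts of the two orientations of selected pairs.
# Returns an n_seqs x (2 * n_pairs) matrix, columns ordered
# (AB, BA) per pair, pairs in canonical alphabetical orientation.
#' @noRd
.pair_counts_per_seq <- function(seqs, pairs, gap = 0L,
                                 skip_initial_met = FALSE) {
  codes <- .encode_set(seqs, skip_initial_met)
  n <- length(codes)
  codes_all <- unlist(lapply(codes, function(x) c(x, -1L)), use.names = FALSE)
  seq_id <- rep.int(seq_len(n), lengths(codes) + 1L)
  w <- gap + 1L
  L <- length(codes_all)
  out <- matrix(0L, nrow = n, ncol = 2L * length(pairs))
  colnames(out) <- as.vector(rbind(pairs, vapply(pairs, function(p) {
    q <- .parse_pair(p); paste0(q[2L], q[1L])
  }, character(1L))))
  if (L <= w) return(out)
  first <- codes_all[seq_len(L - w)]
  second <- codes_all[seq.int(w + 1L, L)]
  starcum <- cumsum(codes_all == -1L)
  has_star <- (starcum[seq.int(w + 1L, L)] - c(0L, starcum)[seq_len(L - w)]) > 0L
  valid <- first >= 1L & second >= 1L & !has_star
  id1 <- seq_id[seq_len(L - w)]
  for (j in seq_along(pairs)) {
    q <- match(.parse_pair(pairs[j]), .AA20)
    sel_ab <- valid & first == q[1L] & second == q[2L]
    sel_ba <- valid & first == q[2L] & second == q[1L]
    out[, 2L * j - 1L] <- tabulate(id1[sel_ab], nbins = n)
    out[, 2L * j] <- tabulate(id1[sel_ba], nbins = n)
  }
  out
}

#' Bootstrap standard errors for selected C190 values
#'
#' Estimates the sampling uncertainty of the C190 of selected pairs by
#' resampling whole sequences with replacement (the sequence, not the
#' residue, is the sampling unit).
#'
#' @param seqs Named character vector of sequences.
#' @param pairs Character vector of 2-letter pair labels (e.g. `"EP"`).
#' @param gap,skip_initial_met Passed to the counting step.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Data frame with one row per pair: `pair`, `n_ab`, `n_ba`,
#'   `c190` (full-set estimate), `boot_se`.
#' @export
bootstrap_c190 <- function(seqs, pairs, gap = 0L, skip_initial_met = FALSE,
                           n_boot = 200L, seed = 1L) {
  gap <- .check_count_scalar(gap, "gap")
  n_boot <- .check_count_scalar(n_boot, "n_boot", min = 2L)
  pairs <- vapply(pairs, function(p) paste(.parse_pair(p), collapse = ""),
                  character(1L), USE.NAMES = FALSE)
  m <- .pair_counts_per_seq(seqs, pairs, gap, skip_initial_met)
  n <- length(seqs)
  full <- colSums(m)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(r) {
      colSums(m[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(m)))
  })
  j <- seq_along(pairs)
  bc <- matrix(c190(boots[2L * j - 1L, , drop = FALSE],
                    boots[2L * j, , drop = FALSE]),
               nrow = length(pairs))
  data.frame(pair = pairs,
             n_ab = unname(full[2L * j - 1L]), n_ba = unname(full[2L * j]),
             c190 = c190(full[2L * j - 1L], full[2L * j]),
             boot_se = apply(bc, 1L, stats::sd, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}
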