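# Dipeptide (and gapped pair) counting.
#
# Internally every protein is encoded as an integer vector: 1..20 for the
# standard residues (alphabetical order), 0 for tolerated non-standard
# letters (B, J, O, U, X, Z), -1 for the hard separator '*'. A whole set is
# counted in one vectorized pass over the concatenation of its members with
# a '*' code inserted between them: any counting window that crosses a
# separator is dropped, so a single separator suffices for every gap.

#' @noRd
.encode_protein <- function(chars) {
  code <- match(chars, .AA20, nomatch = 0L)
  code[chars == "*"] <- -1L
  code
}

#' @noRd
.encode_set <- function(seqs, skip_initial_met = FALSE) {
  s <- toupper(as.character(seqs))
  if (skip_initial_met) s <- sub("^M", "", s)
  lapply(strsplit(s, "", fixed = TRUE), .encode_protein)
}

# Core pass: codes_all is the concatenated coding with -1 separators already
# in place. Returns a length-400 integer vector indexed (first-1)*20 + second.
#' @noRd
.count_codes <- function(codes_all, gap) {
  w <- gap + 1L
  L <- length(codes_all)
  if (L <= w) return(integer(400L))
  first <- codes_all[seq_len(L - w)]
  second <- codes_all[seq.int(w + 1L, L)]
  starcum <- cumsum(codes_all == -1L)
  has_star <- (starcum[seq.int(w + 1L, L)] - c(0L, starcum)[seq_len(L - w)]) > 0L
  valid <- first >= 1L & second >= 1L & !has_star
  tabulate((first[valid] - 1L) * 20L + second[valid], nbins = 400L)
}

#' @noRd
.codes_to_table <- function(codes_list, gap, skip_initial_met, n_sequences) {
  codes_all <- if (length(codes_list))
    unlist(lapply(codes_list, function(x) c(x, -1L)), use.names = FALSE)
  else integer(0L)
  m <- matrix(.count_codes(codes_all, gap), nrow = 20L, ncol = 20L,
              byrow = TRUE, dimnames = list(first = .AA20, second = .AA20))
  structure(m, gap = gap, skip_initial_met = skip_initial_met,
            n_sequences = n_sequences, class = c("dipeptide_counts", "matrix"))
}

#' Count ordered residue pairs in a sequence set
#'
#' Counts every ordered pair of standard residues at positions
#' `(i, i + gap + 1)` across all sequences, with overlapping windows (step
#' 1), so `"AAA"` contributes 2 to the AA cell. At `gap = 0` this is plain
#' dipeptide counting; at `gap > 0` it counts gapped pairs A(X)nB where the
#' n = `gap` intervening letters may be of any type (including non-standard
#' letters) — only the two endpoints must be standard residues. Windows never
#' span sequence boundaries nor cross a `*` separator. Sequences shorter
#' than `gap + 2` contribute nothing.
#'
#' @param seqs Named character vector of protein sequences (a sequence set).
#' @param gap Number of intervening residues (0 = adjacent dipeptides).
#' @param skip_initial_met If `TRUE`, a leading `M` is removed from each
#'   sequence before counting (N-terminal methionine correction). Default
#'   `FALSE`: the initiator methionine bias is observed, not corrected.
#' @return A 20x20 integer matrix of class `"dipeptide_counts"` (rows =
#'   first residue, columns = second residue, alphabetical order) with
#'   attributes `gap`, `skip_initial_met` and `n_sequences`. The grand total
#'   `sum(...)` is the pair universe n_XX.
#' @examples
#' count_pairs(c(s1 = "AGA"))["A", "G"]
#' @export
count_pairs <- function(seqs, gap = 0L, skip_initial_met = FALSE) {
  gap <- .check_count_scalar(gap, "gap")
  stopifnot(is.character(seqs), is.logical(skip_initial_met))
  .codes_to_table(.encode_set(seqs, skip_initial_met), gap,
                  skip_initial_met, length(seqs))
}

#' Marginal totals of a pair count table
#'
#' @param counts A `"dipeptide_counts"` matrix from [count_pairs()] (any
#'   20x20 count matrix is accepted).
#' @return A list with `n_first` (row sums: counts with each residue in the
#'   first position), `n_second` (column sums) and `n_total` (the grand
#'   total n_XX).
#' @export
marginals <- function(counts) {
  counts <- .as_count_matrix(counts)
  list(n_first = rowSums(counts), n_second = colSums(counts),
       n_total = sum(counts))
}

#' @noRd
.as_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !all(dim(counts) == c(20L, 20L)) ||
      !is.numeric(counts) || anyNA(counts) || any(counts < 0))
    stop("`counts` must be a 20x20 non-negative count matrix", call. = FALSE)
  if (is.null(dimnames(counts))) dimnames(counts) <- list(.AA20, .AA20)
  counts
}

#' @export
print.dipeptide_counts <- function(x, ...) {
  cat(sprintf("dipeptide count table: gap=%d, skip_initial_met=%s, %d sequence(s), n_XX=%s\n",
              attr(x, "gap"), attr(x, "skip_initial_met"),
              attr(x, "n_sequences"), format(sum(x), big.mark = ",")))
  print(unclass(x), ...)
  invisible(x)
}
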