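# Random gene mutagenesis and frame-1 translation.
#
# The experiment asks whether random base-level modifications of coding
# sequences change the dipeptide/antidipeptide statistics of their
# translations. Internally, coding sequences are integer base codes
# (A=1, C=2, G=3, T=4) and translation is a single table lookup per codon.

#' @noRd
.encode_dna <- function(s) {
  code <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], .BASES)
  if (anyNA(code))
    stop("coding sequence contains letters outside A/C/G/T", call. = FALSE)
  code
}

#' @noRd
.decode_dna <- function(code) paste(.BASES[code], collapse = "")

#' @noRd
.delete_codes <- function(code, k) {
  code[-sample.int(length(code), k)]
}

#' @noRd
.substitute_codes <- function(code, k) {
  pos <- sample.int(length(code), k)
  # shift each hit base by 1..3 (mod 4): uniform over the 3 other bases,
  # never the original.
  code[pos] <- (code[pos] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L
  code
}

# Codon indices of a base-code vector in frame 1 (trailing 1-2 bases
# dropped); empty for length < 3.
#' @noRd
.codon_idx <- function(code) {
  n3 <- length(code) %/% 3L
  if (n3 == 0L) return(integer(0L))
  i <- seq_len(n3) * 3L
  (code[i - 2L] - 1L) * 16L + (code[i - 1L] - 1L) * 4L + code[i]
}

#' Delete random bases from a coding sequence
#'
#' Removes `k` distinct positions chosen uniformly without replacement,
#' preserving the order of the remaining bases. Deleting a number of bases
#' that is not a multiple of 3 shifts the downstream reading frame.
#'
#' @param cds A single A/C/G/T string.
#' @param k Number of bases to delete (`1 <= k < nchar(cds)`).
#' @param seed Optional seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return The mutated sequence, `nchar(cds) - k` bases long.
#' @export
delete_bases <- function(cds, k, seed = NULL) {
  code <- .encode_dna(cds)
  k <- .check_count_scalar(k, "k", min = 1L)
  if (k >= length(code))
    stop("k must be smaller than the sequence length", call. = FALSE)
  .decode_dna(with_seed(seed, .delete_codes(code, k)))
}

#' Substitute random bases in a coding sequence
#'
#' Picks `k` distinct positions uniformly and replaces each base by one of
#' the 3 other bases, chosen uniformly, so the output differs from the
#' input at exactly `k` positions.
#'
#' @inheritParams delete_bases
#' @param k Number of bases to substitute (`1 <= k <= nchar(cds)`).
#' @return The mutated sequence, same length as the input.
#' @export
substitute_bases <- function(cds, k, seed = NULL) {
  code <- .encode_dna(cds)
  k <- .check_count_scalar(k, "k", min = 1L)
  if (k > length(code))
    stop("k must not exceed the sequence length", call. = FALSE)
  .decode_dna(with_seed(seed, .substitute_codes(code, k)))
}

#' Frame-1 translation under the standard genetic code
#'
#' Translates the forward strand in frame 1, reading codons until fewer
#' than 3 bases remain (trailing 1-2 bases are dropped). Stop codons emit
#' `*` and translation continues to the end of the sequence; downstream,
#' [count_pairs()] treats `*` as a hard separator, so no dipeptide ever
#' spans a stop. Sequences shorter than 3 bases give an empty protein.
#'
#' @param cds A single A/C/G/T string.
#' @return The translated protein as a character string (possibly empty),
#'   over the 20 standard residues plus `*`.
#' @examples
#' translate_cds("ATGGCT")    # "MA"
#' translate_cds("ATGTAAGCT") # "M*A"
#' @export
translate_cds <- function(cds) {
  idx <- .codon_idx(.encode_dna(cds))
  paste(.CODON_AA[idx], collapse = "")
}

#' The classic four-spec mutation preset
#'
#' The preset used by the reference experiment: per gene, mutants carrying
#' 1 or 5 random base deletions, or 10 or 50 random base substitutions.
#'
#' @param n_mutants Mutants generated per gene and spec (default 100).
#' @return A data frame of specs with columns `label`, `kind`, `n_events`,
#'   `n_mutants`, suitable for [mutation_experiment()].
#' @export
default_mutation_specs <- function(n_mutants = 100L) {
  n_mutants <- .check_count_scalar(n_mutants, "n_mutants", min = 1L)
  data.frame(label = c("del1", "del5", "sub10", "sub50"),
             kind = c("delete", "delete", "substitute", "substitute"),
             n_events = c(1L, 5L, 10L, 50L),
             n_mutants = n_mutants,
             stringsAsFactors = FALSE)
}

#' Random mutagenesis experiment on a set of coding sequences
#'
#' Translates the wild-type genes (frame 1, standard code), then for each
#' mutation spec generates `n_mutants` independent mutants of every gene,
#' translates them, pools all mutant translations of the spec, and computes
#' the asymmetry and propensity tables of wild type and each mutant pool.
#' Per-pair differences (mutant minus wild type) are reported for both
#' statistics. Pooling across genes and mutants before computing the
#' statistics mirrors computing C190 on a sequence set.
#'
#' @param genes Named character vector of A/C/G/T coding sequences.
#' @param specs Mutation specs, as from [default_mutation_specs()]. An
#'   empty spec table yields a wild-type-only result. `n_events = 0` is
#'   allowed for `"substitute"` only (identity mutant, a validation hook).
#' @param seed Integer seed; the same seed reproduces the experiment
#'   bit for bit.
#' @param gap Gap used for the pair counting (default 0, adjacent).
#' @param keep_translations If `TRUE`, the wild-type and pooled mutant
#'   protein translations are returned alongside the tables (needed e.g.
#'   to run [fppp_analysis()] on the mutant pools).
#' @return A list of class `"mutation_experiment"` with elements
#'   `wild_type` (list: `counts`, `asymmetry`, `propensity`), `specs`
#'   (named list per spec label with the same structure plus `n_proteins`),
#'   `deltas` (list of two long data frames, `c190` and `propensity`),
#'   `seed`, `n_genes`; with `keep_translations`, each of `wild_type` and
#'   the spec entries also carries a `translations` character vector.
#' @export
mutation_experiment <- function(genes, specs = default_mutation_specs(),
                                seed = 1L, gap = 0L,
                                keep_translations = FALSE) {
  if (length(genes) == 0L) stop("`genes` must not be empty", call. = FALSE)
  stopifnot(is.data.frame(specs),
            all(c("label", "kind", "n_events", "n_mutants") %in% names(specs)))
  if (!all(specs$kind %in% c("delete", "substitute")))
    stop("spec kind must be \"delete\" or \"substitute\"", call. = FALSE)
  if (any(specs$n_events < 0) ||
      any(specs$n_events[specs$kind == "delete"] < 1))
    stop("n_events must be >= 1 (>= 0 only for substitutions)", call. = FALSE)
  gcodes <- lapply(genes, .encode_dna)
  lens <- lengths(gcodes)
  del <- specs$n_events[specs$kind == "delete"]
  if (length(del) && min(lens) <= max(del))
    stop("every gene must be longer than the largest deletion spec",
         call. = FALSE)
  sub <- specs$n_events[specs$kind == "substitute"]
  if (length(sub) && min(lens) < max(sub))
    stop("substitution spec exceeds the shortest gene", call. = FALSE)

  decode <- function(pcodes) {
    vapply(pcodes, function(pc)
      paste(c(.AA20, "*")[replace(pc, pc == -1L, 21L)], collapse = ""),
      character(1L))
  }
  stats_of <- function(pcodes, n_seq) {
    counts <- .codes_to_table(pcodes, gap, FALSE, n_seq)
    out <- list(counts = counts, asymmetry = asymmetry_table(counts),
                propensity = propensity_table(counts))
    if (keep_translations) {
      tr <- decode(pcodes)
      names(tr) <- sprintf("mut_%06d", seq_along(tr))
      out$translations <- tr
    }
    out
  }
  wt_pcodes <- lapply(gcodes, function(g) .CODON_PCODE[.codon_idx(g)])
  wt <- stats_of(wt_pcodes, length(genes))
  if (keep_translations) names(wt$translations) <- names(genes)

  spec_res <- with_seed(seed, {
    out <- vector("list", nrow(specs))
    names(out) <- specs$label
    for (i in seq_len(nrow(specs))) {
      k <- specs$n_events[i]
      mutate <- if (specs$kind[i] == "delete") .delete_codes else .substitute_codes
      pcodes <- vector("list", length(gcodes) * specs$n_mutants[i])
      pos <- 0L
      for (g in gcodes) {
        for (m in seq_len(specs$n_mutants[i])) {
          pos <- pos + 1L
          mg <- if (k == 0L) g else mutate(g, k)
          pcodes[[pos]] <- .CODON_PCODE[.codon_idx(mg)]
        }
      }
      out[[i]] <- c(stats_of(pcodes, pos), list(n_proteins = pos))
    }
    out
  })

  deltas_c190 <- do.call(rbind, lapply(names(spec_res), function(lab) {
    a <- spec_res[[lab]]$asymmetry
    data.frame(spec = lab, pair = a$pair,
               wt_c190 = wt$asymmetry$c190, mut_c190 = a$c190,
               delta = a$c190 - wt$asymmetry$c190,
               stringsAsFactors = FALSE)
  }))
  deltas_prop <- do.call(rbind, lapply(names(spec_res), function(lab) {
    p <- spec_res[[lab]]$propensity
    data.frame(spec = lab, first = p$first, second = p$second,
               wt_propensity = wt$propensity$propensity,
               mut_propensity = p$propensity,
               delta = p$propensity - wt$propensity$propensity,
               stringsAsFactors = FALSE)
  }))

  structure(list(wild_type = wt, specs = spec_res,
                 deltas = list(c190 = deltas_c190, propensity = deltas_prop),
                 seed = seed, n_genes = length(genes)),
            class = "mutation_experiment")
}

#' @export
print.mutation_experiment <- function(x, ...) {
  cat(sprintf("mutation experiment: %d gene(s), %d spec(s), seed=%s\n",
              x$n_genes, length(x$specs), format(x$seed)))
  for (lab in names(x$specs))
    cat(sprintf("  %-6s pooled mutant proteins: %d\n", lab,
                x$specs[[lab]]$n_proteins))
  invisible(x)
}
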