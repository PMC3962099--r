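# TSV report writers and command-style entry points tying the modules into
# the full pipeline. All files are tab-separated with '#'-prefixed metadata
# header lines (tool version, configuration, seed), so they stay
# machine-parseable and byte-identical across reruns of the same inputs.
# Progress/log output goes to standard error via message().

#' @noRd
.meta_lines <- function(...) {
  kv <- list(...)
  c(paste0("# dipasym ", as.character(utils::packageVersion("dipasym"))),
    vapply(names(kv), function(k) paste0("# ", k, "=", format(kv[[k]])),
           character(1L), USE.NAMES = FALSE))
}

#' @noRd
.write_tsv <- function(df, path, meta, rounding = NULL) {
  if (!is.null(rounding))
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- round(df[[j]], rounding)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a pair count table as TSV
#'
#' The 20x20 table (rows = first residue, columns = second residue,
#' alphabetical) preceded by metadata lines recording gap, counting policy
#' and totals. [read_count_tsv()] restores the table with its attributes.
#'
#' @param counts A `"dipeptide_counts"` matrix.
#' @param path File path.
#' @return `write_count_tsv()`: invisibly, `path`. `read_count_tsv()`: the
#'   restored `"dipeptide_counts"` matrix.
#' @export
write_count_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "dipeptide_counts"))
  df <- data.frame(first = .AA20, unclass(counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path,
             .meta_lines(gap = attr(counts, "gap"),
                         skip_initial_met = attr(counts, "skip_initial_met"),
                         n_sequences = attr(counts, "n_sequences"),
                         n_total = sum(counts)))
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    v <- sub(paste0("^# ", key, "="), "", grep(paste0("^# ", key, "="),
                                               meta, value = TRUE))
    if (length(v) != 1L) stop("missing metadata field ", key, call. = FALSE)
    v
  }
  tab <- utils::read.delim(text = paste(lines[!startsWith(lines, "#")],
                                        collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(first = tab[[1L]], second = colnames(tab)[-1L])
  structure(m, gap = as.integer(get_meta("gap")),
            skip_initial_met = as.logical(get_meta("skip_initial_met")),
            n_sequences = as.integer(get_meta("n_sequences")),
            class = c("dipeptide_counts", "matrix"))
}

#' Count pairs in a FASTA file and write the table
#'
#' Pipeline command: read a protein FASTA, count pairs, export the 20x20
#' TSV. Logs the number of sequences and the pair total to standard error.
#'
#' @param input Protein FASTA path.
#' @param output Output TSV path.
#' @param gap,skip_initial_met See [count_pairs()].
#' @return Invisibly, the `"dipeptide_counts"` matrix.
#' @export
cmd_count <- function(input, output, gap = 0L, skip_initial_met = FALSE) {
  seqs <- read_fasta_protein(input)
  counts <- count_pairs(seqs, gap = gap, skip_initial_met = skip_initial_met)
  if (length(seqs) == 0L)
    warning("input contains no sequences; writing an all-zero table",
            call. = FALSE)
  n_excluded <- sum(vapply(.encode_set(seqs, skip_initial_met),
                           function(x) sum(x == 0L), integer(1L)))
  message(sprintf("counted %d sequence(s): n_XX=%d at gap=%d (%d non-standard letters excluded)",
                  length(seqs), sum(counts), gap, n_excluded))
  write_count_tsv(counts, output)
  invisible(counts)
}

#' Full asymmetry analysis of a FASTA file
#'
#' Pipeline command: count pairs, then write three reports named
#' `<out_prefix>_asymmetry.tsv` (190 rows: pair, counts, C190, signed
#' C190), `<out_prefix>_propensity.tsv` (400 rows) and
#' `<out_prefix>_residue_averages.tsv` (20 rows, `mean(SE)` format).
#'
#' @param input Protein FASTA path.
#' @param out_prefix Path prefix for the three reports.
#' @param gap,skip_initial_met See [count_pairs()].
#' @param rounding Decimal places in the reports (default 2).
#' @return Invisibly, a list with `counts`, `asymmetry`, `propensity`,
#'   `residue_averages`.
#' @export
cmd_asymmetry <- function(input, out_prefix, gap = 0L,
                          skip_initial_met = FALSE, rounding = 2L) {
  seqs <- read_fasta_protein(input)
  counts <- count_pairs(seqs, gap = gap, skip_initial_met = skip_initial_met)
  at <- asymmetry_table(counts)
  pt <- propensity_table(counts)
  ra <- residue_averages(at)
  meta <- .meta_lines(input = basename(input), gap = gap,
                      skip_initial_met = skip_initial_met,
                      n_sequences = length(seqs), n_total = sum(counts))
  .write_tsv(at[, c("pair", "n_ab", "n_ba", "c190", "signed_c190")],
             paste0(out_prefix, "_asymmetry.tsv"), meta, rounding)
  .write_tsv(pt[, c("first", "second", "n", "propensity")],
             paste0(out_prefix, "_propensity.tsv"), meta, rounding)
  fmt <- function(m, s) ifelse(is.na(m), "NA",
                               sprintf("%.*f(%.*f)", rounding, m, rounding, s))
  .write_tsv(data.frame(residue = ra$residue, n_pairs = ra$n_pairs,
                        mean_c190 = fmt(ra$mean_c190, ra$std_error),
                        stringsAsFactors = FALSE),
             paste0(out_prefix, "_residue_averages.tsv"), meta)
  message(sprintf("asymmetry analysis of %d sequence(s): %d/190 pairs defined",
                  length(seqs), sum(at$defined)))
  invisible(list(counts = counts, asymmetry = at, propensity = pt,
                 residue_averages = ra))
}

#' FPPP subsampling report for a FASTA file
#'
#' Pipeline command: run [fppp_analysis()] and write one row per pair with
#' a `mean(SE)` column per subset size plus a final `all` column holding
#' the full-set C190.
#'
#' @param input Protein FASTA path.
#' @param output Output TSV path.
#' @param subset_sizes Integer vector of subset sizes.
#' @param seed Partition seed.
#' @param gap,skip_initial_met See [count_pairs()].
#' @param rounding Decimal places (default 2).
#' @return Invisibly, the long-format FPPP data frame.
#' @export
cmd_fppp <- function(input, output, subset_sizes, seed = 1L, gap = 0L,
                     skip_initial_met = FALSE, rounding = 2L) {
  seqs <- read_fasta_protein(input)
  fp <- fppp_analysis(seqs, subset_sizes, seed = seed, gap = gap,
                      skip_initial_met = skip_initial_met)
  full <- asymmetry_table(count_pairs(seqs, gap = gap,
                                      skip_initial_met = skip_initial_met))
  wide <- data.frame(pair = full$pair, stringsAsFactors = FALSE)
  for (size in unique(fp$subset_size)) {
    d <- fp[fp$subset_size == size, ]
    wide[[paste0("size_", size)]] <-
      ifelse(d$n_defined == 0, "NA",
             sprintf("%.*f(%.*f)", rounding, d$mean_c190, rounding,
                     d$std_error))
  }
  wide$all <- ifelse(full$defined,
                     sprintf("%.*f", rounding, full$c190), "NA")
  .write_tsv(wide, output,
             .meta_lines(input = basename(input), seed = seed, gap = gap,
                         skip_initial_met = skip_initial_met,
                         subset_sizes = paste(subset_sizes, collapse = ",")))
  message(sprintf("FPPP on %d sequence(s) at sizes {%s}", length(seqs),
                  paste(subset_sizes, collapse = ", ")))
  invisible(fp)
}

#' Mutagenesis experiment report for a nucleotide FASTA file
#'
#' Pipeline command: run [mutation_experiment()] on the coding sequences
#' and write `<out_prefix>_c190.tsv` (pair, wild-type C190, one column per
#' spec, and the deltas) and `<out_prefix>_propensity.tsv` (same layout
#' for the 400 ordered pairs).
#'
#' @param input Nucleotide FASTA path.
#' @param out_prefix Path prefix for the reports.
#' @param n_mutants Mutants per gene and spec.
#' @param seed Experiment seed.
#' @param gap Counting gap.
#' @param rounding Decimal places (default 2).
#' @return Invisibly, the `"mutation_experiment"` result.
#' @export
cmd_mutate <- function(input, out_prefix, n_mutants = 100L, seed = 1L,
                       gap = 0L, rounding = 2L) {
  genes <- read_fasta_nucleotide(input)
  mx <- mutation_experiment(genes, default_mutation_specs(n_mutants),
                            seed = seed, gap = gap)
  meta <- .meta_lines(input = basename(input), seed = seed, gap = gap,
                      n_mutants = n_mutants, n_genes = length(genes))
  c_wide <- data.frame(pair = mx$wild_type$asymmetry$pair,
                       wt = mx$wild_type$asymmetry$c190,
                       stringsAsFactors = FALSE)
  p_wide <- data.frame(first = mx$wild_type$propensity$first,
                       second = mx$wild_type$propensity$second,
                       wt = mx$wild_type$propensity$propensity,
                       stringsAsFactors = FALSE)
  for (lab in names(mx$specs)) {
    c_wide[[lab]] <- mx$specs[[lab]]$asymmetry$c190
    c_wide[[paste0("delta_", lab)]] <- c_wide[[lab]] - c_wide$wt
    p_wide[[lab]] <- mx$specs[[lab]]$propensity$propensity
    p_wide[[paste0("delta_", lab)]] <- p_wide[[lab]] - p_wide$wt
  }
  .write_tsv(c_wide, paste0(out_prefix, "_c190.tsv"), meta, rounding)
  .write_tsv(p_wide, paste0(out_prefix, "_propensity.tsv"), meta, rounding)
  message(sprintf("mutation experiment: %d gene(s) x %d mutants x %d specs",
                  length(genes), n_mutants, length(mx$specs)))
  invisible(mx)
}

#' Generate a synthetic sequence set and write it as FASTA
#'
#' Pipeline command: build a fixture preset ([make_preset()]), draw
#' sequences from its Markov model, write them as FASTA and (optionally)
#' the model as TSV.
#'
#' @param preset `"symmetric"` or `"table3_asymmetric"`.
#' @param n_seqs,length Set dimensions.
#' @param seed Generation seed.
#' @param fasta_out Output FASTA path.
#' @param model_out Optional output path for the model TSV.
#' @return Invisibly, the generated named character vector.
#' @export
cmd_simulate <- function(preset, n_seqs, length, seed = 1L, fasta_out,
                         model_out = NULL) {
  px <- make_preset(preset, seed = seed)
  seqs <- generate_proteins(px$model, n_seqs, length, seed = seed)
  write_fasta(seqs, fasta_out)
  if (!is.null(model_out)) write_markov_model(px$model, model_out)
  message(sprintf("wrote %d x %d-residue sequences from preset \"%s\" (seed %s)",
                  n_seqs, length, preset, format(seed)))
  invisible(seqs)
}
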