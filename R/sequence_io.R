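#' Read a protein FASTA file
#'
#' Reads a multi-record FASTA file of amino-acid sequences. Residues are
#' upper-cased; gap characters (`-`) and whitespace are stripped. Besides the
#' 20 standard one-letter codes the letters `B`, `J`, `O`, `U`, `X`, `Z` and
#' the separator `*` are tolerated (they are retained in the sequence but
#' never take part in pair counting, see [count_pairs()]). Any other letter
#' is an error, as is a duplicated record id.
#'
#' @param path Path to a FASTA file.
#' @param label Optional label for the set; defaults to the file name.
#' @return A named character vector of sequences (one element per record,
#'   names are the full FASTA headers), with attribute `label`. This named
#'   character vector is the "sequence set" container used throughout the
#'   package.
#' @seealso [write_fasta()], [read_fasta_nucleotide()]
#' @export
read_fasta_protein <- function(path, label = basename(path)) {
  x <- Biostrings::readBStringSet(path)
  ids <- names(x)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  s <- toupper(gsub("[-[:space:]]", "", as.character(x)))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYBJOUXZ*]*$", s)
  if (!all(ok))
    stop("record(s) with unexpected letters: ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  names(s) <- ids
  attr(s, "label") <- label
  s
}

#' Read a nucleotide FASTA file
#'
#' Reads coding (DNA) sequences. Bases are upper-cased and `U` is mapped to
#' `T`. Records containing any letter outside `A`/`C`/`G`/`T` after that
#' mapping are skipped with a warning by default, or raise an error in
#' strict mode.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, a record with invalid letters is an error
#'   instead of being skipped.
#' @return A named character vector of A/C/G/T sequences.
#' @export
read_fasta_nucleotide <- function(path, strict = FALSE) {
  x <- Biostrings::readBStringSet(path)
  ids <- names(x)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  s <- chartr("U", "T", toupper(gsub("[[:space:]]", "", as.character(x))))
  bad <- grepl("[^ACGT]", s)
  if (any(bad)) {
    if (strict)
      stop("record(s) with non-ACGTU letters: ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    warning("skipping ", sum(bad), " record(s) with non-ACGTU letters: ",
            paste(ids[bad], collapse = ", "), call. = FALSE)
    s <- s[!bad]
    ids <- ids[!bad]
  }
  names(s) <- ids
  s
}

#' Write sequences to FASTA
#'
#' Writes a named character vector of sequences (protein or nucleotide) as
#' plain multi-record FASTA, wrapped at 60 characters per line.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs))
  if (length(seqs) > 0L && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all sequences must have non-empty names", call. = FALSE)
  x <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}
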