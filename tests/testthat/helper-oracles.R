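# Shared oracles and random fixtures, independent of the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force reference counter: explicit double loop over every window.
naive_count_pairs <- function(seqs, gap = 0, skip_initial_met = FALSE) {
  m <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  w <- gap + 1
  for (s in seqs) {
    if (skip_initial_met) s <- sub("^M", "", s)
    ch <- strsplit(toupper(s), "")[[1]]
    L <- length(ch)
    if (L <= w) next
    for (i in seq_len(L - w)) {
      a <- ch[i]
      b <- ch[i + w]
      if (!(a %in% AA20) || !(b %in% AA20)) next
      if (any(ch[i:(i + w)] == "*")) next
      m[a, b] <- m[a, b] + 1L
    }
  }
  m
}

# Random protein set with a sprinkling of non-standard letters and stops.
random_protein_set <- function(n, len, seed, p_odd = 0.02) {
  set.seed(seed)
  alphabet <- c(AA20, "X", "B", "U", "*")
  prob <- c(rep((1 - 2 * p_odd) / 20, 20), p_odd / 2, p_odd / 4, p_odd / 8,
            p_odd + p_odd / 8)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  names(out) <- sprintf("rp_%04d", seq_len(n))
  out
}

# Random strictly positive count table (all pairs defined).
random_count_table <- function(seed, lambda = 40) {
  set.seed(seed)
  counts <- count_pairs(character(0))
  counts[] <- as.integer(rpois(400, lambda))
  counts
}

random_dna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(seqs, wrap = 60) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(seq_along(seqs), function(i) {
    body <- seqs[[i]]
    starts <- seq(1, max(nchar(body), 1), by = wrap)
    c(paste0(">", names(seqs)[i]),
      if (nchar(body) > 0) substring(body, starts, pmin(starts + wrap - 1,
                                                        nchar(body))))
  }))
  writeLines(lines, path)
  path
}
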