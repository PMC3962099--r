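test_that("deletion removes exactly k bases preserving order", {
  set.seed(61)
  for (k in c(1, 5, 20)) {
    cds <- random_dna(60, seed = 61 + k)
    mut <- delete_bases(cds, k, seed = k)
    expect_equal(nchar(mut), 60 - k)
  }
  # forced single deletion: only three outcomes, all subsequences
  outs <- vapply(1:50, function(i) delete_bases("ATG", 1, seed = i),
                 character(1))
  expect_true(all(outs %in% c("TG", "AG", "AT")))
  expect_error(delete_bases("ATG", 3), "smaller than")
  expect_error(delete_bases("ATG", 0), "k")
})

test_that("substitution changes exactly k positions", {
  cds <- random_dna(80, seed = 62)
  for (k in c(1, 10, 80)) {
    mut <- substitute_bases(cds, k, seed = k)
    expect_equal(nchar(mut), 80)
    d <- sum(strsplit(cds, "")[[1]] != strsplit(mut, "")[[1]])
    expect_equal(d, k)
  }
  # k = length on a homopolymer: no position keeps its base
  expect_false(grepl("A", substitute_bases("AAAA", 4, seed = 3)))
  expect_error(substitute_bases("ATG", 4), "exceed")
})

test_that("deleted positions and replacement bases are uniform", {
  set.seed(63)
  cds <- random_dna(20, seed = 63)
  base <- strsplit(cds, "")[[1]]
  pos <- integer(0)
  repl <- character(0)
  for (i in 1:4000) {
    mutd <- strsplit(delete_bases(cds, 1), "")[[1]]
    pos <- c(pos, which(c(mutd, "$") != base)[1])
    muts <- strsplit(substitute_bases(cds, 1), "")[[1]]
    j <- which(muts != base)
    repl <- c(repl, muts[j])
  }
  # deleting any base inside a run of equal letters yields the same string,
  # first detectable at the run's end, so compare against the run-length
  # distribution over run ends rather than uniform raw positions
  runs <- rle(base)
  ends <- cumsum(runs$lengths)
  expected <- runs$lengths / sum(runs$lengths)
  obs <- tabulate(match(pos, ends), length(ends))
  expect_gt(chisq.test(obs, p = expected)$p.value, 1e-4)
  # replacement bases: each of the four letters appears as a replacement
  # with probability proportional to how often it is an alternative
  p_repl <- vapply(c("A", "C", "G", "T"),
                   function(b) sum(base != b) / (3 * length(base)),
                   numeric(1))
  obs_repl <- table(factor(repl, levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(obs_repl, p = p_repl)$p.value, 1e-4)
})

test_that("frame-1 translation matches an independent implementation on all codons", {
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  mine <- vapply(codons, translate_cds, character(1), USE.NAMES = FALSE)
  oracle <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1), USE.NAMES = FALSE)
  expect_identical(mine, oracle)
  expect_equal(sum(mine == "*"), 3)
})

test_that("translation drops trailing bases and continues through stops", {
  expect_identical(translate_cds("ATGGCT"), "MA")
  expect_identical(translate_cds("ATGGCTG"), "MA")
  expect_identical(translate_cds("ATGGCTGC"), "MA")
  expect_identical(translate_cds("AT"), "")
  expect_identical(translate_cds("ATGTAAGCT"), "M*A")
  # the stop acts as a separator downstream: no dipeptide spans it
  expect_equal(sum(count_pairs(c(s = translate_cds("ATGTAAGCT")))), 0L)
})

test_that("a single deletion shifts every codon at or after its position", {
  cds <- random_dna(90, seed = 64)
  wt <- strsplit(translate_cds(cds), "")[[1]]
  for (p in c(1, 30, 61, 89)) {
    mut <- paste(strsplit(cds, "")[[1]][-p], collapse = "")
    mu <- strsplit(translate_cds(mut), "")[[1]]
    first_codon <- ceiling(p / 3)
    if (first_codon > 1)
      expect_identical(mu[seq_len(first_codon - 1)],
                       wt[seq_len(first_codon - 1)])
    # downstream codons are read out of frame: identity would be a fluke
    expect_false(identical(mu, wt[-length(wt)]) && p < 85)
  }
})

test_that("identity mutants reproduce wild-type tables exactly", {
  prot <- random_protein_set(12, 40, seed = 65, p_odd = 0)
  genes <- reverse_translate(prot, seed = 66)
  specs <- data.frame(label = "ident", kind = "substitute", n_events = 0L,
                      n_mutants = 3L)
  mx <- mutation_experiment(genes, specs, seed = 67)
  expect_equal(sum(unclass(mx$specs$ident$counts)),
               3 * sum(unclass(mx$wild_type$counts)))
  expect_equal(mx$specs$ident$asymmetry$c190, mx$wild_type$asymmetry$c190)
  d <- mx$deltas$c190$delta
  expect_true(all(d[!is.na(d)] == 0))
  expect_identical(is.na(d), !mx$wild_type$asymmetry$defined)
})

test_that("the mutation experiment is seed-reproducible and validates input", {
  prot <- random_protein_set(6, 30, seed = 68, p_odd = 0)
  genes <- reverse_translate(prot, seed = 69)
  specs <- default_mutation_specs(n_mutants = 2)
  m1 <- mutation_experiment(genes, specs, seed = 70, keep_translations = TRUE)
  m2 <- mutation_experiment(genes, specs, seed = 70, keep_translations = TRUE)
  expect_identical(m1, m2)
  expect_equal(m1$specs$del1$n_proteins, 12)
  expect_named(m1$specs, c("del1", "del5", "sub10", "sub50"))
  expect_length(m1$specs$sub50$translations, 12)

  # empty spec table: wild-type only
  m0 <- mutation_experiment(genes, specs[0, ], seed = 1)
  expect_length(m0$specs, 0)
  expect_equal(nrow(m0$wild_type$asymmetry), 190)

  expect_error(mutation_experiment(character(0)), "empty")
  expect_error(
    mutation_experiment(c(g = "ATGATG"),
                        data.frame(label = "d", kind = "delete",
                                   n_events = 6L, n_mutants = 1L)),
    "longer than")
})

test_that("degenerate genes translate to nothing and give all-zero mutant tables", {
  specs <- data.frame(label = "del1", kind = "delete", n_events = 1L,
                      n_mutants = 5L)
  mx <- mutation_experiment(c(g = "ATG"), specs, seed = 2)
  expect_equal(sum(unclass(mx$specs$del1$counts)), 0L)
  expect_equal(unname(unclass(mx$wild_type$counts)["M", ]), rep(0L, 20))
})
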