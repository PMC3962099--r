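test_that("markov_model validates its inputs", {
  expect_s3_class(uniform_markov_model(), "markov_model")
  bad <- matrix(1 / 20, 20, 20)
  bad[1, 1] <- 0.5
  expect_error(markov_model(bad), "sum to 1")
  expect_error(markov_model(matrix(1 / 10, 10, 10)), "20x20")
  expect_error(markov_model(matrix(1 / 20, 20, 20), initial = rep(1, 20)),
               "probability")
})

test_that("a deterministic chain generates a constant sequence", {
  tm <- diag(20)
  init <- c(1, rep(0, 19))  # all mass on A, A -> A forever
  m <- markov_model(tm, initial = init)
  s <- generate_proteins(m, 3, 8, seed = 1)
  expect_equal(unname(s), rep("AAAAAAAA", 3))
})

test_that("generated residue and transition frequencies match the model", {
  m <- uniform_markov_model()
  s <- generate_proteins(m, 200, 250, seed = 71)
  freq <- table(factor(strsplit(paste(s, collapse = ""), "")[[1]],
                       levels = AA20))
  expect_gt(chisq.test(freq)$p.value, 1e-4)

  # empirical transitions of a biased model within 3 binomial SE (pooled)
  p <- make_preset("table3_asymmetric")
  s2 <- generate_proteins(p$model, 400, 300, seed = 72)
  ct <- count_pairs(s2)
  m2 <- marginals(ct)
  tm <- p$model$transition
  emp <- unclass(ct) / m2$n_first
  se <- sqrt(tm * (1 - tm) / m2$n_first)
  expect_true(all(abs(emp - tm) <= 4 * se + 1e-12))
})

test_that("stationary distributions solve pi T = pi", {
  expect_equal(unname(stationary_distribution(uniform_markov_model())),
               rep(1 / 20, 20))

  # doubly stochastic: uniform stationary distribution
  set.seed(73)
  ds <- matrix(1 / 20, 20, 20)
  for (i in 1:50) {  # symmetric perturbations keep both margins stochastic
    idx <- sample(20, 2)
    eps <- runif(1, 0, 0.005)
    ds[idx[1], idx[1]] <- ds[idx[1], idx[1]] - eps
    ds[idx[1], idx[2]] <- ds[idx[1], idx[2]] + eps
    ds[idx[2], idx[2]] <- ds[idx[2], idx[2]] - eps
    ds[idx[2], idx[1]] <- ds[idx[2], idx[1]] + eps
  }
  expect_equal(unname(stationary_distribution(markov_model(ds))),
               rep(1 / 20, 20), tolerance = 1e-10)

  # random chain vs power-iteration oracle
  set.seed(74)
  tm <- matrix(rgamma(400, 2), 20, 20)
  tm <- tm / rowSums(tm)
  pi_ <- stationary_distribution(markov_model(tm))
  v <- rep(1 / 20, 20)
  for (i in 1:5000) v <- as.vector(v %*% tm)
  expect_equal(unname(pi_), v, tolerance = 1e-10)
  expect_equal(as.vector(pi_ %*% tm), unname(pi_), tolerance = 1e-12)
})

test_that("expected pair counts follow the closed form", {
  m <- uniform_markov_model()
  e <- expected_pair_count(m, gap = 0, length = 41)
  expect_equal(unname(e), matrix(40 / 400, 20, 20))
  e5 <- expected_pair_count(m, gap = 5, length = 41)
  expect_equal(unname(e5), matrix(35 / 400, 20, 20))

  # empirical gapped counts near analytic (Poisson-scale tolerance)
  p <- make_preset("table3_asymmetric")
  n <- 800
  s <- generate_proteins(p$model, n, 120, seed = 75)
  e5 <- expected_pair_count(p$model, gap = 5, length = 120)
  obs <- unclass(count_pairs(s, gap = 5))
  expect_true(all(abs(obs - n * e5) <= 4 * sqrt(n * e5) + 1e-9))
})

test_that("analytic c190 vanishes under detailed balance", {
  m <- uniform_markov_model()
  pairs <- apply(combn(AA20, 2), 2, paste, collapse = "")
  vals <- vapply(sample(pairs, 12), function(p) analytic_c190(m, p),
                 numeric(1))
  expect_equal(unname(vals), rep(0, 12), tolerance = 1e-10)
})

test_that("presets are self-consistent and deterministic", {
  p <- make_preset("table3_asymmetric")
  expect_equal(nrow(p$engineered_pairs), 7)
  for (i in seq_len(nrow(p$engineered_pairs))) {
    expect_equal(analytic_c190(p$model, p$engineered_pairs$pair[i]),
                 p$engineered_pairs$expected_c190[i])
    expect_lt(abs(p$engineered_pairs$expected_c190[i] -
                  p$engineered_pairs$target_c190[i]), 0.5)
  }
  # dominant orientation carries the sign
  expect_lt(analytic_c190(p$model, "EP", signed = TRUE), 0)  # PE dominates
  expect_gt(analytic_c190(p$model, "IP", signed = TRUE), 0)  # IP dominates

  s <- make_preset("symmetric")
  expect_equal(s$engineered_pairs$expected_c190, rep(0, 8), tolerance = 1e-9)

  expect_identical(make_preset("table3_asymmetric", seed = 5),
                   make_preset("table3_asymmetric", seed = 5))
  expect_error(make_preset("nope"), "unknown preset")
})

test_that("reverse translation is the right inverse of translation", {
  expect_identical(unname(reverse_translate(c(s = "MW"), seed = 1)),
                   "ATGTGG")
  prot <- random_protein_set(15, 45, seed = 76, p_odd = 0)
  cds <- reverse_translate(prot, seed = 77)
  expect_identical(vapply(cds, translate_cds, character(1)),
                   setNames(prot, names(cds)))
  expect_error(reverse_translate(c(s = "MA*G")), "stop-free")
})

test_that("reverse translation honors codon usage weights", {
  # uniform default: leucine's six codons roughly equally used
  prot <- setNames(paste(rep("L", 3000), collapse = ""), "polyL")
  cds <- reverse_translate(prot, seed = 78)
  used <- substring(cds, seq(1, 9000, 3), seq(3, 9000, 3))
  expect_gt(chisq.test(table(used))$p.value, 1e-4)
  expect_equal(sort(unique(used)),
               sort(c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG")))

  # degenerate weights force a single codon
  w <- list(L = c(TTA = 0, TTG = 0, CTT = 1, CTC = 0, CTA = 0, CTG = 0))
  cds1 <- reverse_translate(c(s = "LLL"), codon_weights = w, seed = 79)
  expect_identical(unname(cds1), "CTTCTTCTT")
  expect_error(reverse_translate(c(s = "L"),
                                 codon_weights = list(L = c(TTA = 1))),
               "invalid codon weights")
})

test_that("markov models round-trip through the TSV format", {
  p <- make_preset("table3_asymmetric")
  path <- tempfile(fileext = ".tsv")
  write_markov_model(p$model, path)
  back <- read_markov_model(path)
  expect_equal(back$transition, p$model$transition, tolerance = 1e-12)
  expect_equal(back$initial, p$model$initial, tolerance = 1e-12)
})
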