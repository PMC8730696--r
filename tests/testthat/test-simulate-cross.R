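test_that("zero map distance gives perfectly co-inherited markers", {
  pop <- simulate_f2(200, c(1e6, 5e6, 9e6), 5e6, 1e7, cm_per_mb = 0, seed = 1)
  expect_true(all(pop$genotypes[, 1] == pop$genotypes[, 2]))
  expect_true(all(pop$genotypes[, 2] == pop$genotypes[, 3]))
})

test_that("gamete recombinant fraction matches the Haldane closed form", {
  # d = 0.2 Morgans -> r = (1 - exp(-0.4))/2 = 0.16484
  r_true <- 0.5 * (1 - exp(-0.4))
  expect_equal(r_true, 0.164840, tolerance = 1e-6)
  set.seed(11)
  g <- bulkmapr:::sim_gametes(10000, r_true)
  obs <- mean(g[, 1] != g[, 2])
  bounds <- binom_bounds99(r_true, 10000)
  expect_gte(obs, bounds[1])
  expect_lte(obs, bounds[2])
})

test_that("genotype and phenotype frequencies are Mendelian at large n", {
  pop <- simulate_f2(10000, c(1e6, 2.5e7), 2.5e7, 5e7, seed = 3)
  dosage <- pop$genotypes[, 2]          # the causal marker
  for (k in 0:2) {
    p <- c(0.25, 0.5, 0.25)[k + 1]
    bounds <- binom_bounds99(p, 10000)
    expect_gte(mean(dosage == k), bounds[1])
    expect_lte(mean(dosage == k), bounds[2])
  }
  p_mut <- mean(pop$phenotype == "mutant")
  bounds <- binom_bounds99(0.25, 10000)
  expect_gte(p_mut, bounds[1])
  expect_lte(p_mut, bounds[2])
  # complete penetrance: phenotype iff P1-homozygous at the causal locus
  expect_identical(pop$phenotype == "mutant", pop$causal_dosage == 2L)
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_f2(100, seq(1e6, 1e7, 1e6), 5e6, 1e7, seed = 99)
  b <- simulate_f2(100, seq(1e6, 1e7, 1e6), 5e6, 1e7, seed = 99)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotype, b$phenotype)
})

test_that("configuration errors are caught", {
  expect_error(simulate_f2(10, numeric(0), 5e6, 1e7), "non-empty")
  expect_error(simulate_f2(10, c(2e6, 1e6), 5e6, 1e7), "increasing")
  expect_error(simulate_f2(10, c(1e6, 2e7), 5e6, 1e7), "within")
  expect_error(simulate_f2(10, c(1e6, 5e6), 2e7, 1e7), "causal")
})

test_that("bulks are disjoint subsets of the right phenotype class", {
  pop <- simulate_f2(400, seq(1e6, 2e7, 1e6), 1e7, 2e7, seed = 5)
  b <- make_bulks(pop, 30, 30, seed = 6)
  expect_length(intersect(b$mut, b$wt), 0)
  expect_true(all(pop$phenotype[b$mut] == "mutant"))
  expect_true(all(pop$phenotype[b$wt] == "wildtype"))

  b0 <- make_bulks(pop, 0, 0)
  expect_length(b0$mut, 0)
  expect_length(b0$wt, 0)

  expect_error(make_bulks(pop, 1e6, 30), "mutant")
  expect_error(make_bulks(pop, 30, 1e6), "wildtype")
})

test_that("bulk allele frequencies follow the conditional Mendelian values", {
  # mutant bulk at the causal marker is fixed for P1
  pop <- simulate_f2(600, c(1e6, 1e7, 1.9e7), 1e7, 2e7, seed = 8)
  b <- make_bulks(pop, 30, 30, seed = 9)
  f <- bulk_frequencies(pop, b)
  expect_equal(f$freq_mut[f$pos == 1e7], 1.0)

  # wildtype bulk: conditional on not-mutant, genotypes het:P2hom = 2:1,
  # so the P1-allele frequency is (2 * 1/2) / 3 = 1/3
  set.seed(10)
  freqs <- replicate(200, {
    bb <- make_bulks(pop, 30, 30)
    bulk_frequencies(pop, bb)$freq_wt[2]
  })
  expect_equal(mean(freqs), 1 / 3, tolerance = 0.01)
})

test_that("bulk read counts are binomial at the bulk allele frequency", {
  # fixed-frequency populations built directly: dosage 2 / 0 / 1 everywhere
  fake_pop <- function(dosage, m) {
    structure(list(
      genotypes = matrix(dosage, nrow = 60, ncol = m),
      markers = tibble::tibble(chrom = "c1", pos = seq_len(m) * 1000),
      phenotype = rep(c("mutant", "wildtype"), each = 30),
      n_f2 = 60L
    ), class = "f2_population")
  }
  bulks <- structure(list(mut = 1:30, wt = 31:60,
                          bulk_size_mut = 30L, bulk_size_wt = 30L),
                     class = "f2_bulks")

  # frequency 1: count equals depth everywhere
  bc1 <- simulate_bulk_reads(fake_pop(2L, 50), bulks, 30, "fixed", seed = 1)
  expect_true(all(bc1$mut_count == bc1$depth))
  # frequency 0
  bc0 <- simulate_bulk_reads(fake_pop(0L, 50), bulks, 30, "fixed", seed = 1)
  expect_true(all(bc0$mut_count == 0))
  # frequency 1/2 at fixed depth 30 over 10 000 sites: mean near 15
  bch <- simulate_bulk_reads(fake_pop(1L, 10000), bulks, 30, "fixed", seed = 2)
  se <- sqrt(30 * 0.25) / sqrt(10000)
  expect_lt(abs(mean(bch$mut_count) - 15), 2.576 * se)
  # counts never exceed depth
  expect_true(all(bch$mut_count <= bch$depth))
})
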