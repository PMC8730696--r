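toy_records <- function() {
  tibble::tibble(
    chrom = "c1", pos = 1:6 * 100,
    parent1_allele = c("A", "A", "A", "A", "A", "A"),
    parent2_allele = c("G", "G", "G", "G", "G", "G"),
    parent1_hom = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    parent2_hom = TRUE,
    depth_p1 = c(10, 10, 10, 10, 10, 10),
    depth_mut = c(10, 2, 10, 10, 10, 10),
    depth_wt = c(10, 10, 2, 10, 10, 10)
  )
}

test_that("variant filtering applies the support and homozygosity rules", {
  # 6 records: 2 low-support, 1 het parent, 3 clean -> 3 retained
  recs <- toy_records()
  kept <- filter_variants(recs)
  expect_equal(kept$pos, c(100, 400, 600))
  rep <- attr(kept, "filter_report")
  expect_equal(rep$n[rep$reason == "low_support"], 2)
  expect_equal(rep$n[rep$reason == "uninformative_parents"], 1)

  # idempotent and a subset of the input
  again <- filter_variants(kept)
  expect_equal(again, kept, ignore_attr = TRUE)
  expect_true(all(kept$pos %in% recs$pos))

  # missing parental evidence warns and drops
  recs$parent1_allele[1] <- NA
  expect_warning(k2 <- filter_variants(recs), "missing parental")
  expect_equal(k2$pos, c(400, 600))
})

test_that("SNP-index and delta obey their definitions and bounds", {
  expect_equal(snp_index(30, 0), 0)
  expect_equal(snp_index(30, 30), 1)
  expect_equal(snp_index(40, 12), 0.3)
  expect_true(is.na(snp_index(0, 0)))
  expect_error(snp_index(10, 12), "0, depth")

  expect_equal(delta_index(0.5, 0.5), 0)
  expect_equal(delta_index(0.98, 0.32), 0.66)
  expect_equal(delta_index(0, 1), -1)
  expect_error(delta_index(1.2, 0), "0, 1")
})

test_that("window means equal the unweighted mean over member SNPs", {
  pts <- make_points(pos = c(1e4, 3e4, 6e4, 9e4, 15e4),
                     delta = c(0.1, 0.2, 0.3, 0.4, 0.5))
  prof <- window_profile(pts, window_size = 2e5, step = 2e4, min_snps = 3,
                         chrom_lengths = c(c1 = 2e5))
  # single full-chromosome window holds all 5 SNPs
  expect_equal(nrow(prof), 1)
  expect_equal(prof$n_snps, 5L)
  expect_equal(prof$delta, 0.3)

  # one SNP per window; sparse windows flagged missing
  pts2 <- make_points(pos = 1e5, delta = 0.4)
  prof2 <- window_profile(pts2, window_size = 2e5, step = 2e4, min_snps = 1,
                          chrom_lengths = c(c1 = 6e5))
  covering <- prof2$start <= 1e5 & prof2$end >= 1e5
  expect_true(all(prof2$delta[covering] == 0.4))
  expect_true(all(prof2$missing[!covering]))
  expect_true(all(is.na(prof2$delta[!covering])))

  # windowed means stay within the member-site range
  set.seed(20)
  pts3 <- make_points(pos = sort(sample(1e6, 300)),
                      delta = runif(300, -1, 1))
  prof3 <- window_profile(pts3, 2e5, 2e4, min_snps = 1,
                          chrom_lengths = c(c1 = 1e6))
  expect_true(all(prof3$delta >= min(pts3$delta) - 1e-12, na.rm = TRUE))
  expect_true(all(prof3$delta <= max(pts3$delta) + 1e-12, na.rm = TRUE))
  expect_true(all(diff(prof3$start) == 2e4))

  expect_error(window_profile(make_points(c(5, 1), c(0, 0))), "sort")
})

test_that("the null envelope is centred, depth-monotone and seeded", {
  set.seed(30)
  d <- bulkmapr:::sim_null_window_delta(1, 10000, 30, 30, 30, "poisson")
  expect_lt(abs(median(d)), 0.02)

  e10 <- null_envelope(30, 30, 10, n_snps = c(5, 20), n_sims = 4000, seed = 1)
  e100 <- null_envelope(30, 30, 100, n_snps = c(5, 20), n_sims = 4000, seed = 1)
  expect_true(all(e100$q99 <= e10$q99))
  expect_true(all(e100$q95 <= e10$q95))
  expect_true(all(e10$q99 >= e10$q95))

  expect_identical(
    null_envelope(30, 30, 30, n_snps = 10, n_sims = 500, seed = 7),
    null_envelope(30, 30, 30, n_snps = 10, n_sims = 500, seed = 7)
  )
  expect_warning(null_envelope(30, 30, 30, n_snps = 10, n_sims = 50),
                 "unstable")
})

test_that("region calling merges contiguous significant windows", {
  # abutting (non-overlapping) windows so the merge rule is visible
  prof <- tibble::tibble(
    chrom = "c1",
    start = seq(1, 1 + 5 * 2e4, by = 2e4),
    end = seq(1, 1 + 5 * 2e4, by = 2e4) + 2e4 - 1,
    n_snps = 20L,
    index_mut = 0.9, index_wt = 0.3,
    delta = c(0.1, 0.6, 0.7, 0.1, 0.1, 0.65),
    missing = FALSE
  )
  env <- tibble::tibble(n_snps = 20L, q95 = 0.3, q99 = 0.4, n_sims = 1000L)

  regions <- call_regions(prof, env, level = 99)
  expect_equal(nrow(regions), 2)           # overlapping pair merges, singleton apart
  expect_equal(regions$n_windows, c(2L, 1L))
  expect_equal(regions$peak_delta[1], 0.7)
  expect_equal(regions$start[1], prof$start[2])
  expect_equal(regions$end[1], prof$end[3])

  # nothing significant -> empty call set
  none <- call_regions(dplyr::mutate(prof, delta = 0.1), env, 99)
  expect_equal(nrow(none), 0)
})

test_that("an end-to-end synthetic scan recovers the causal locus", {
  pop <- simulate_f2(200, seq(1e4, 1e7, 1e4), 5e6, 1e7, seed = 41)
  bulks <- make_bulks(pop, 30, 30, seed = 42)
  bc <- simulate_bulk_reads(pop, bulks, 30, seed = 43)
  scan <- bsa_scan(bc, 30, 30, n_sims = 2000, chrom_lengths = c(chr1 = 1e7),
                   seed = 44)
  expect_gt(nrow(scan$regions), 0)
  hit <- scan$regions$start <= 5e6 & scan$regions$end >= 5e6
  expect_true(any(hit))
  # mutant bulk is near fixation at the causal site
  expect_gt(scan$points$index_mut[scan$points$pos == 5e6], 0.9)
  # all indices and deltas within bounds
  expect_true(all(scan$points$index_mut >= 0 & scan$points$index_mut <= 1,
                  na.rm = TRUE))
  expect_true(all(abs(scan$points$delta) <= 1, na.rm = TRUE))
})
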