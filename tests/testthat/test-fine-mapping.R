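five_markers <- tibble::tibble(
  marker = paste0("m", 1:5), chrom = "c6",
  pos = c(100, 200, 300, 400, 500) * 1000
)

test_that("a panel without informative recombinants spans all markers", {
  panel <- tibble::tibble(
    phenotype = c("mutant", "wildtype"),
    m1 = c("P1", "H"), m2 = c("P1", "H"), m3 = c("P1", "H"),
    m4 = c("P1", "H"), m5 = c("P1", "H")
  )
  iv <- infer_interval(panel, five_markers)
  expect_equal(iv$left, 1e5)
  expect_equal(iv$right, 5e5)
  expect_equal(iv$n_markers_in, 5L)
})

test_that("mutant recombinants move the interval bound past their breakpoint", {
  # mutant het left of m3, P1hom from m3 on: markers m1-m2 are excluded
  panel <- tibble::tibble(
    phenotype = "mutant",
    m1 = "H", m2 = "H", m3 = "P1", m4 = "P1", m5 = "P1"
  )
  iv <- infer_interval(panel, five_markers)
  expect_equal(iv$left, 2e5)            # flanking excluded marker
  expect_equal(iv$left_marker, "m2")
  expect_equal(iv$right, 5e5)

  # matches the brute-force exclusion oracle
  calls <- bulkmapr:::normalize_calls(panel, five_markers$marker)
  excl <- oracle_excluded(calls, panel$phenotype, FALSE)
  expect_equal(unname(excl), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("wildtype individuals only exclude in homozygous-line panels", {
  panel <- tibble::tibble(
    phenotype = "wildtype",
    m1 = "P1", m2 = "P1", m3 = "P2", m4 = "P2", m5 = "P2"
  )
  # segregating panel: wildtype P1hom is uninformative
  iv <- infer_interval(panel, five_markers, homozygous_lines = FALSE)
  expect_equal(iv$n_markers_in, 5L)
  # fixed lines: P1hom wildtype excludes m1-m2
  iv2 <- infer_interval(panel, five_markers, homozygous_lines = TRUE)
  expect_equal(iv2$left, 2e5)
})

test_that("inconsistent panels raise an error naming the individuals", {
  panel <- tibble::tibble(
    phenotype = c("mutant", "mutant"),
    m1 = c("P2", "P1"), m2 = c("P1", "P2"), m3 = c("P2", "P1"),
    m4 = c("P1", "P2"), m5 = c("P2", "P2")
  )
  expect_error(infer_interval(panel, five_markers), "inconsistent")
})

test_that("interval inference is sound and monotone on simulated line panels", {
  markers <- tibble::tibble(marker = sprintf("s%02d", 1:21), chrom = "c6",
                            pos = seq(2e7, 3e7, length.out = 21))
  for (seed in 1:10) {
    sim <- simulate_recombinant_lines(80, markers, 2.5e7, seed = seed)
    iv_full <- infer_interval(sim$panel, markers, homozygous_lines = TRUE)
    # causal position always inside
    expect_lte(iv_full$left, 2.5e7)
    expect_gte(iv_full$right, 2.5e7)
    # adding individuals never widens the interval
    iv_half <- infer_interval(sim$panel[1:40, ], markers,
                              homozygous_lines = TRUE)
    expect_gte(iv_full$left, iv_half$left)
    expect_lte(iv_full$right, iv_half$right)
    # brute-force oracle agreement on the exclusion set
    calls <- bulkmapr:::normalize_calls(sim$panel, markers$marker)
    excl <- oracle_excluded(calls, sim$panel$phenotype, TRUE)
    open <- which(!excl)
    expect_equal(iv_full$n_markers_in, length(open))
  }
})

test_that("co-segregation counts mismatches and ignores missing calls", {
  expect_true(cosegregation(c("P1", "P1", "H", "P2"),
                            c("mutant", "mutant", "wildtype", "wildtype"))$perfect)
  r <- cosegregation(c("P1", "H", "H"), c("mutant", "mutant", "wildtype"))
  expect_false(r$perfect)
  expect_equal(r$mismatches, 1)
  expect_equal(cosegregation(c("P1", NA), c("mutant", "mutant"))$n_informative, 1)

  # a perfectly co-segregating marker lies inside the inferred interval
  markers <- tibble::tibble(marker = sprintf("s%02d", 1:11), chrom = "c6",
                            pos = seq(1e6, 2e6, length.out = 11))
  sim <- simulate_recombinant_lines(60, markers, 1.5e6, seed = 3)
  iv <- infer_interval(sim$panel, markers, homozygous_lines = TRUE)
  cosg <- vapply(markers$marker, function(m) {
    cosegregation(sim$panel[[m]], sim$panel$phenotype)$perfect
  }, logical(1))
  for (m in markers$marker[cosg]) {
    p <- markers$pos[markers$marker == m]
    expect_true(p >= iv$left && p <= iv$right)
  }

  # shuffled phenotypes break co-segregation with high probability
  set.seed(9)
  shuffled <- sample(sim$panel$phenotype)
  expect_gt(cosegregation(sim$panel$s06, shuffled)$mismatches, 0)
})

test_that("interval lengths honour both coordinate conventions", {
  expect_equal(interval_length(c(37945500, 38129705), "flank")$bp, 184205)
  expect_equal(interval_length(c(37945500, 38129705), "flank")$kb, 184.2)
  expect_equal(interval_length(c(38062128, 38062543), "inclusive")$bp, 416)
  expect_equal(interval_length(c(7, 7), "inclusive")$bp, 1)
  expect_equal(interval_length(c(7, 7), "flank")$bp, 0)
  expect_error(interval_length(c(10, 5)), "exceeds")
})

test_that("gene counting overlaps by at least one bp, strand-agnostic", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5), chrom = "c6",
    start = c(100, 900, 1500, 2000, 3001),
    end = c(500, 1200, 1800, 3000, 3500),
    strand = c("+", "-", "+", "-", "+")
  )
  iv <- tibble::tibble(chrom = "c6", left = 1000, right = 2500)
  hit <- genes_in_interval(genes, iv)
  expect_equal(hit$gene_id, c("g2", "g3", "g4"))

  # gene starting just past the interval end is excluded
  iv2 <- tibble::tibble(chrom = "c6", left = 1000, right = 3000)
  expect_false("g5" %in% genes_in_interval(genes, iv2)$gene_id)

  expect_equal(nrow(genes_in_interval(genes[0, ], iv)), 0)
  expect_error(genes_in_interval(genes, tibble::tibble(chrom = "c9",
                                                       left = 1, right = 2)),
               "absent")
})
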