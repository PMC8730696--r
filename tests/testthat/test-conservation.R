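test_that("column diversity matches explicit pair enumeration", {
  aln <- tibble::tibble(
    label = c("a", "b", "c", "d"),
    sequence = c("AAAN", "ATA-", "TTAN", "TAAC")
  )
  got <- column_diversity(aln)
  want <- vapply(1:4, function(j) {
    oracle_column_diversity(substring(aln$sequence, j, j))
  }, numeric(1))
  expect_equal(got, want)

  # canonical cases
  mono <- tibble::tibble(label = letters[1:5],
                         sequence = rep("A", 5))
  expect_equal(column_diversity(mono), 0)
  distinct <- tibble::tibble(label = letters[1:5],
                             sequence = c("A", "C", "G", "T", "-"))
  expect_equal(column_diversity(distinct), 1)
  # (A,A,T,T): 4 of 6 pairs mismatch
  aatt <- tibble::tibble(label = letters[1:4],
                         sequence = c("A", "A", "T", "T"))
  expect_equal(column_diversity(aatt), 2 / 3)
  # all-N column is missing
  alln <- tibble::tibble(label = letters[1:3], sequence = rep("N", 3))
  expect_true(is.na(column_diversity(alln)))
})

test_that("diversity is invariant under row reordering", {
  fam <- simulate_promoter_family(ancestral_length = 400, seed = 12)
  d1 <- column_diversity(fam$alignment)
  d2 <- column_diversity(fam$alignment[sample(nrow(fam$alignment)), ])
  expect_equal(d1, d2)
})

test_that("window counts and means follow the reference-space definition", {
  fam <- simulate_promoter_family(ancestral_length = 5000, seed = 13)
  prof <- window_diversity(fam$alignment)
  expect_equal(nrow(prof), 496)                  # floor((5000-50)/10)+1
  expect_equal(diff(prof$start), rep(10L, 495))

  # constant per-column diversity c gives every window c
  const <- tibble::tibble(
    label = c("r1", "r2"),
    sequence = c(strrep("A", 200), strrep("C", 200))
  )
  p2 <- window_diversity(const)
  expect_true(all(p2$diversity == 1))

  zero <- tibble::tibble(label = c("r1", "r2"),
                         sequence = rep(strrep("A", 200), 2))
  expect_true(all(window_diversity(zero)$diversity == 0))

  # window means bounded by member columns
  div <- column_diversity(fam$alignment)
  expect_true(all(prof$diversity >= min(div) - 1e-12))
  expect_true(all(prof$diversity <= max(div) + 1e-12))

  short <- tibble::tibble(label = c("a", "b"),
                          sequence = c("ACGT", "ACGA"))
  expect_warning(ps <- window_diversity(short), "shorter")
  expect_equal(nrow(ps), 1)
})

test_that("conserved-region calling merges runs below the threshold", {
  fam <- simulate_promoter_family(ancestral_length = 1000, seed = 14)
  prof <- window_diversity(fam$alignment)

  expect_equal(nrow(call_conserved(
    structure(dplyr::mutate(prof, diversity = 0.5), class = class(prof))
  )), 0)

  all0 <- call_conserved(
    structure(dplyr::mutate(prof, diversity = 0), class = class(prof))
  )
  expect_equal(nrow(all0), 1)
  expect_equal(all0$start, min(prof$start))
  expect_equal(all0$end, max(prof$end))
})

test_that("synthetic conserved blocks are recovered with good overlap", {
  blocks <- list(c(1001, 1600), c(3001, 3700))
  fam <- simulate_promoter_family(
    ancestral_length = 5000, conserved_blocks = blocks,
    background_rate = 0.3, conserved_rate = 0.03, seed = 15
  )
  regions <- call_conserved(window_diversity(fam$alignment))
  expect_gte(nrow(regions), 2)
  for (b in blocks) {
    j <- vapply(seq_len(nrow(regions)), function(i) {
      jaccard_iv(b, c(regions$start[i], regions$end[i]))
    }, numeric(1))
    expect_gte(max(j), 0.6)
  }
})

test_that("reference gaps shift alignment columns but not reference coordinates", {
  # gapless alignment: identity mapping
  plain <- tibble::tibble(label = c("ref", "x"),
                          sequence = c("ACGTACGT", "ACGAACGA"))
  expect_equal(bulkmapr:::map_ref_to_aln(plain, "ref"), 1:8)

  # ten leading gaps in the reference: columns shift by 10
  gapped <- tibble::tibble(
    label = c("ref", "x"),
    sequence = c(paste0(strrep("-", 10), "ACGTACGT"),
                 paste0(strrep("T", 10), "ACGAACGA"))
  )
  expect_equal(bulkmapr:::map_ref_to_aln(gapped, "ref"), 11:18)
})

test_that("a deletion placed inside a conserved block is fully covered", {
  fam <- simulate_promoter_family(
    ancestral_length = 5000,
    conserved_blocks = list(c(1001, 1600), c(3001, 3700)),
    seed = 16
  )
  ov <- sv_overlap(fam$alignment, c(3100, 3515))
  expect_equal(attr(ov, "fraction_covered"), 1.0)
  expect_equal(sum(ov$overlap_bp), 416)

  expect_error(sv_overlap(fam$alignment, c(4900, 5200)), "outside")
  expect_error(sv_overlap(fam$alignment, c(300, 200)), "exceeds")
})
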