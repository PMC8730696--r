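# Independent brute-force oracles used to freeze expected values.

# chi-squared GOF by direct formula (no continuity correction)
oracle_chisq <- function(obs, ratio) {
  e <- sum(obs) * ratio / sum(ratio)
  sum((obs - e)^2 / e)
}

# column diversity by explicit pair enumeration (gap = state, N dropped)
oracle_column_diversity <- function(chars) {
  chars <- chars[chars != "N"]
  if (length(chars) < 2) return(NA_real_)
  pairs <- utils::combn(length(chars), 2)
  mean(chars[pairs[1, ]] != chars[pairs[2, ]])
}

# region pi by averaging Hamming distances over all haplotype pairs
# (complete 0/1 haplotype matrix: sites x n), per bp of region length
oracle_region_pi <- function(haps, region_length) {
  n <- ncol(haps)
  if (n < 2) return(NA_real_)
  pairs <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    sum(haps[, pairs[1, k]] != haps[, pairs[2, k]])
  }, numeric(1))
  mean(d) / region_length
}

# exclusion-based interval by brute force: a marker survives iff no
# individual contradicts the recessive model there
oracle_excluded <- function(calls, phenotypes, homozygous_lines) {
  apply(calls, 2, function(g) {
    any((phenotypes == "mutant" & !is.na(g) & g != "P1") |
          (homozygous_lines & phenotypes == "wildtype" & !is.na(g) & g == "P1"))
  })
}

# binomial 99% bounds for an observed proportion
binom_bounds99 <- function(p, n) {
  hw <- 2.576 * sqrt(p * (1 - p) / n)
  c(p - hw, p + hw)
}

# Jaccard index of two 1-based inclusive intervals
jaccard_iv <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  uni <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - inter
  inter / uni
}

# quick wide-to-long constructor for window-profile tests
make_points <- function(pos, delta, chrom = "c1",
                        index_mut = NULL, index_wt = NULL) {
  tibble::tibble(
    chrom = chrom, pos = pos,
    depth_mut = 30L, depth_wt = 30L,
    index_mut = index_mut %||% pmin(pmax(delta, 0), 1),
    index_wt = index_wt %||% 0,
    delta = delta
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
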