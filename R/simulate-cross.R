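#' Simulate an F2 population segregating a monogenic recessive locus
#'
#' Generates F2 individuals from a cross between a mutant parent (P1, e.g. an
#' all-flesh-fruit line) and a wild-type parent (P2). Each individual is the
#' union of two independent gametes; along a gamete, the allele switches
#' between adjacent loci with the recombinant fraction given by the Haldane
#' map function \eqn{r = (1 - e^{-2d})/2}, where the map distance `d` (in
#' Morgans) is derived from the physical spacing via `cm_per_mb`. The
#' phenotype is fully penetrant monogenic recessive: an individual is
#' `"mutant"` if and only if it is homozygous for the P1 allele at
#' `causal_position`. The causal locus is simulated jointly with the markers
#' even when it is not itself a marker.
#'
#' @param n_f2 Number of F2 individuals.
#' @param marker_positions Strictly increasing marker positions (bp) within
#'   `[1, chrom_length]`.
#' @param causal_position Position (bp) of the causal locus.
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param cm_per_mb Recombination rate in centimorgans per megabase used to
#'   turn physical spacing into map distance. Default 4, a rate typical of
#'   the gene-rich euchromatic chromosome arms where loci of this kind are
#'   mapped (genome-wide plant averages are lower, but recombination is
#'   concentrated in euchromatin).
#' @param seed Optional integer seed; fixed seed gives identical populations.
#'
#' @return An `f2_population`: list with `genotypes` (integer matrix,
#'   individuals x markers, P1-allele dosage 0/1/2), `markers` (tibble
#'   `chrom`, `pos`), `causal_dosage`, `phenotype` (`"mutant"`/`"wildtype"`),
#'   and the simulation parameters. `as_tibble()` gives a long tidy view.
#'
#' @examples
#' pop <- simulate_f2(200, marker_positions = seq(1e6, 2e7, by = 1e6),
#'                    causal_position = 1.05e7, chrom_length = 2e7, seed = 1)
#' table(pop$phenotype)
#' @export
simulate_f2 <- function(n_f2, marker_positions, causal_position,
                        chrom_length, chrom = "chr1", cm_per_mb = 4,
                        seed = NULL) {
  n_f2 <- check_count(n_f2, "n_f2", min = 1)
  marker_positions <- as.numeric(marker_positions)
  if (length(marker_positions) == 0) abort("`marker_positions` must be non-empty.")
  if (any(diff(marker_positions) <= 0)) {
    abort("`marker_positions` must be strictly increasing.")
  }
  if (min(marker_positions) < 1 || max(marker_positions) > chrom_length) {
    abort("`marker_positions` must lie within [1, chrom_length].")
  }
  if (causal_position < 1 || causal_position > chrom_length) {
    abort("`causal_position` must lie within the chromosome.")
  }
  if (cm_per_mb < 0) abort("`cm_per_mb` must be non-negative.")
  local_seed(seed)

  # simulate causal locus together with the markers on one ordered axis
  loci <- sort(unique(c(marker_positions, causal_position)))
  causal_idx <- match(causal_position, loci)
  marker_idx <- match(marker_positions, loci)

  d <- diff(loci) / 1e6 * cm_per_mb / 100           # Morgans between loci
  r <- 0.5 * (1 - exp(-2 * d))                      # Haldane, no interference
  gametes <- sim_gametes(2L * n_f2, r)              # P1-allele indicator
  dosage <- gametes[seq_len(n_f2), , drop = FALSE] +
    gametes[n_f2 + seq_len(n_f2), , drop = FALSE]

  causal_dosage <- dosage[, causal_idx]
  structure(
    list(
      genotypes = dosage[, marker_idx, drop = FALSE],
      markers = tibble::tibble(chrom = chrom, pos = marker_positions),
      causal_position = causal_position,
      causal_dosage = causal_dosage,
      phenotype = ifelse(causal_dosage == 2L, "mutant", "wildtype"),
      chrom_length = chrom_length,
      cm_per_mb = cm_per_mb,
      n_f2 = n_f2,
      seed = seed
    ),
    class = "f2_population"
  )
}

# n gametes over loci separated by recombinant fractions r (length m-1);
# returns integer matrix n x m of P1-allele indicators
sim_gametes <- function(n, r) {
  m <- length(r) + 1L
  g <- matrix(0L, n, m)
  g[, 1] <- rbinom(n, 1L, 0.5)
  for (j in seq_len(m - 1L)) {
    flip <- rbinom(n, 1L, r[j])
    g[, j + 1L] <- bitwXor(g[, j], flip)
  }
  g
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("F2 population: %d individuals, %d markers on %s (%g bp)\n",
              x$n_f2, nrow(x$markers), x$markers$chrom[1], x$chrom_length))
  ph <- table(x$phenotype)
  cat("  phenotypes:", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @method as_tibble f2_population
#' @export
as_tibble.f2_population <- function(x, ...) {
  tibble::tibble(
    individual = rep(seq_len(x$n_f2), times = nrow(x$markers)),
    chrom = x$markers$chrom[1],
    pos = rep(x$markers$pos, each = x$n_f2),
    dosage_p1 = as.vector(x$genotypes),
    genotype = c("P2hom", "het", "P1hom")[as.vector(x$genotypes) + 1L],
    phenotype = rep(x$phenotype, times = nrow(x$markers))
  )
}

#' Draw phenotype-selected bulks from an F2 population
#'
#' Selects disjoint random subsets of individuals from the mutant and
#' wild-type phenotype classes, emulating the pooling of extreme segregants
#' for bulked-segregant sequencing (30 + 30 progeny in the motivating
#' design).
#'
#' @param population An `f2_population` from [simulate_f2()].
#' @param bulk_size_mut,bulk_size_wt Individuals per bulk (default 30 each).
#' @param seed Optional integer seed.
#' @return An `f2_bulks` list with integer index vectors `mut` and `wt` into
#'   the population, plus the sizes requested.
#' @examples
#' pop <- simulate_f2(300, seq(1e6, 2e7, 1e6), 1e7, 2e7, seed = 1)
#' bulks <- make_bulks(pop, 30, 30, seed = 2)
#' @export
make_bulks <- function(population, bulk_size_mut = 30, bulk_size_wt = 30,
                       seed = NULL) {
  stopifnot(inherits(population, "f2_population"))
  bulk_size_mut <- check_count(bulk_size_mut, "bulk_size_mut")
  bulk_size_wt <- check_count(bulk_size_wt, "bulk_size_wt")
  local_seed(seed)
  idx_mut <- which(population$phenotype == "mutant")
  idx_wt <- which(population$phenotype == "wildtype")
  if (length(idx_mut) < bulk_size_mut) {
    abort(sprintf(
      "Cannot sample %d mutant individuals: only %d available.",
      bulk_size_mut, length(idx_mut)
    ))
  }
  if (length(idx_wt) < bulk_size_wt) {
    abort(sprintf(
      "Cannot sample %d wildtype individuals: only %d available.",
      bulk_size_wt, length(idx_wt)
    ))
  }
  structure(
    list(
      mut = sort(sample(idx_mut, bulk_size_mut)),
      wt = sort(sample(idx_wt, bulk_size_wt)),
      bulk_size_mut = bulk_size_mut,
      bulk_size_wt = bulk_size_wt
    ),
    class = "f2_bulks"
  )
}

#' True P1-allele frequency of each bulk at every marker
#'
#' @param population An `f2_population`.
#' @param bulks An `f2_bulks`.
#' @return Tibble `chrom`, `pos`, `freq_mut`, `freq_wt`: the fraction of
#'   bulk chromosomes carrying the mutant-parent (P1) allele.
#' @export
bulk_frequencies <- function(population, bulks) {
  stopifnot(inherits(population, "f2_population"), inherits(bulks, "f2_bulks"))
  freq_of <- function(idx) {
    if (length(idx) == 0) return(rep(NA_real_, nrow(population$markers)))
    colSums(population$genotypes[idx, , drop = FALSE]) / (2 * length(idx))
  }
  tibble::tibble(
    chrom = population$markers$chrom,
    pos = population$markers$pos,
    freq_mut = freq_of(bulks$mut),
    freq_wt = freq_of(bulks$wt)
  )
}

#' Simulate pooled short-read allele counts for two bulks
#'
#' For every marker and each bulk, draws a sequencing depth (fixed or
#' Poisson-distributed around `mean_depth`) and a mutant-parent allele count
#' from `Binomial(depth, bulk allele frequency)`, emulating whole-genome
#' resequencing of the two pooled DNA samples at roughly 30-fold coverage.
#'
#' @param population An `f2_population`.
#' @param bulks An `f2_bulks` from [make_bulks()].
#' @param mean_depth Mean reads per site per bulk (default 30).
#' @param depth_model `"poisson"` (depth ~ Poisson(mean_depth)) or `"fixed"`.
#' @param seed Optional integer seed.
#' @return A tibble (`bulk_counts`) in long form with columns `chrom`, `pos`,
#'   `bulk` (`"mut"`/`"wt"`), `depth`, `mut_count`. Feed to
#'   [snp_index_points()] for the per-site SNP-index table.
#' @examples
#' pop <- simulate_f2(300, seq(1e6, 2e7, 1e6), 1e7, 2e7, seed = 1)
#' bulks <- make_bulks(pop, seed = 2)
#' counts <- simulate_bulk_reads(pop, bulks, seed = 3)
#' @export
simulate_bulk_reads <- function(population, bulks, mean_depth = 30,
                                depth_model = c("poisson", "fixed"),
                                seed = NULL) {
  depth_model <- match.arg(depth_model)
  if (bulks$bulk_size_mut == 0 || bulks$bulk_size_wt == 0) {
    abort("Both bulks must be non-empty to simulate reads.")
  }
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  local_seed(seed)
  freq <- bulk_frequencies(population, bulks)
  m <- nrow(freq)
  draw <- function(f) {
    depth <- switch(depth_model,
      poisson = rpois(m, mean_depth),
      fixed = rep(as.integer(round(mean_depth)), m)
    )
    tibble::tibble(depth = depth, mut_count = rbinom(m, depth, f))
  }
  out <- dplyr::bind_rows(
    dplyr::bind_cols(freq[c("chrom", "pos")], bulk = "mut", draw(freq$freq_mut)),
    dplyr::bind_cols(freq[c("chrom", "pos")], bulk = "wt", draw(freq$freq_wt))
  )
  dplyr::arrange(out, .data$chrom, .data$pos, .data$bulk)
}
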