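#' Filter a variant table for bulked-segregant analysis
#'
#' Retains variants that are informative for a two-parent bulk design:
#' both parents homozygous for different alleles, and every sample's read
#' support at least `min_support` (three reads in the motivating design).
#' Records with missing parental fields are dropped with a warning and
#' counted. Order is preserved and the filter is idempotent.
#'
#' @param records Tibble with columns `parent1_allele`, `parent2_allele`
#'   (single bases, `NA` = missing evidence), `parent1_hom`, `parent2_hom`
#'   (logical) and one or more read-support columns selected by
#'   `support_cols`.
#' @param min_support Minimum supporting reads per sample (default 3).
#' @param support_cols Tidyselect expression for the per-sample support
#'   columns; default all columns starting with `"depth"`.
#' @return The retained rows, with a `filter_report` attribute (tibble of
#'   reasons and counts for the removals).
#' @examples
#' recs <- tibble::tibble(
#'   chrom = "c1", pos = 1:3,
#'   parent1_allele = c("A", "A", "A"), parent2_allele = c("G", "G", "A"),
#'   parent1_hom = TRUE, parent2_hom = TRUE,
#'   depth_mut = c(10, 2, 10), depth_wt = 10
#' )
#' filter_variants(recs)
#' @export
filter_variants <- function(records, min_support = 3,
                            support_cols = dplyr::starts_with("depth")) {
  req <- c("parent1_allele", "parent2_allele", "parent1_hom", "parent2_hom")
  if (!all(req %in% names(records))) {
    abort(paste("`records` must have columns:", paste(req, collapse = ", ")))
  }
  sup <- dplyr::select(records, {{ support_cols }})
  if (ncol(sup) == 0) abort("No read-support columns selected.")

  missing_parent <- is.na(records$parent1_allele) | is.na(records$parent2_allele) |
    is.na(records$parent1_hom) | is.na(records$parent2_hom)
  if (any(missing_parent)) {
    warn(sprintf("%d record(s) dropped for missing parental fields.",
                 sum(missing_parent)))
  }
  informative <- !missing_parent &
    records$parent1_hom & records$parent2_hom &
    records$parent1_allele != records$parent2_allele
  supported <- rowSums(as.matrix(sup) < min_support, na.rm = FALSE) == 0
  supported[is.na(supported)] <- FALSE
  keep <- informative & supported

  report <- tibble::tibble(
    reason = c("missing_parent", "uninformative_parents", "low_support", "retained"),
    n = c(
      sum(missing_parent),
      sum(!missing_parent & !informative),
      sum(informative & !supported),
      sum(keep)
    )
  )
  out <- records[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' SNP-index of a bulk at one site
#'
#' The SNP-index is the fraction of reads in a bulk that carry the
#' mutant-parent allele: `mut_count / depth`. Sites with zero depth get
#' `NA` and are excluded from window profiles.
#'
#' @param depth Read depth (vectorized).
#' @param mut_count Reads carrying the mutant-parent allele.
#' @return Numeric vector in `[0, 1]` (or `NA`).
#' @examples
#' snp_index(c(30, 40, 0), c(30, 12, 0))
#' @export
snp_index <- function(depth, mut_count) {
  if (any(mut_count > depth, na.rm = TRUE) || any(mut_count < 0, na.rm = TRUE)) {
    abort("`mut_count` must lie in [0, depth].")
  }
  ifelse(depth > 0, mut_count / depth, NA_real_)
}

#' Delta SNP-index
#'
#' Difference between the mutant-bulk and wild-type-bulk SNP-indices; near
#' zero genome-wide and pushed towards +1 around a recessive locus selected
#' into the mutant bulk.
#'
#' @param index_mut,index_wt SNP-indices in `[0, 1]`.
#' @return `index_mut - index_wt`, in `[-1, 1]`.
#' @examples
#' delta_index(0.98, 0.32)
#' @export
delta_index <- function(index_mut, index_wt) {
  if (any(index_mut < 0 | index_mut > 1, na.rm = TRUE) ||
      any(index_wt < 0 | index_wt > 1, na.rm = TRUE)) {
    abort("SNP-indices must lie in [0, 1].")
  }
  index_mut - index_wt
}

#' Per-site SNP-index table from long bulk counts
#'
#' Pivots a long `bulk_counts` table (one row per site per bulk) into the
#' per-site form the window scan consumes, computing both bulk indices and
#' their difference.
#'
#' @param bulk_counts Tibble `chrom`, `pos`, `bulk` (`"mut"`/`"wt"`),
#'   `depth`, `mut_count`, e.g. from [simulate_bulk_reads()] or
#'   [read_bulk_counts()].
#' @return Tibble `chrom`, `pos`, `depth_mut`, `depth_wt`, `index_mut`,
#'   `index_wt`, `delta`, sorted by position.
#' @export
snp_index_points <- function(bulk_counts) {
  wide <- tidyr::pivot_wider(
    bulk_counts,
    id_cols = c("chrom", "pos"),
    names_from = "bulk", values_from = c("depth", "mut_count")
  )
  dplyr::arrange(
    dplyr::transmute(
      wide,
      chrom = .data$chrom, pos = .data$pos,
      depth_mut = .data$depth_mut, depth_wt = .data$depth_wt,
      index_mut = snp_index(.data$depth_mut, .data$mut_count_mut),
      index_wt = snp_index(.data$depth_wt, .data$mut_count_wt),
      delta = .data$index_mut - .data$index_wt
    ),
    .data$chrom, .data$pos
  )
}

#' Sliding-window profile of the delta SNP-index
#'
#' Averages per-site values over fixed-size windows tiled from position 1
#' with a fixed step (200-kb windows advanced by 20 kb in the motivating
#' analysis). The window value is the unweighted mean over the SNPs whose
#' position falls in `[start, start + window_size)`; windows holding fewer
#' than `min_snps` usable sites are flagged `missing` and excluded from
#' region calling. No smoothing or interpolation bridges empty windows.
#'
#' @param points Per-site tibble from [snp_index_points()]; must be sorted
#'   by `(chrom, pos)`.
#' @param window_size Window width in bp (default 200000).
#' @param step Step between window starts in bp (default 20000); must divide
#'   `window_size`.
#' @param min_snps Minimum usable SNPs per window (default 3).
#' @param chrom_lengths Optional named chromosome lengths; defaults to the
#'   last SNP position per chromosome.
#' @return A `bsa_profile` tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `index_mut`, `index_wt`, `delta`, `missing`, with the parameters as
#'   attributes.
#' @export
window_profile <- function(points, window_size = 200000, step = 20000,
                           min_snps = 3, chrom_lengths = NULL) {
  if (is.unsorted(points$pos[points$chrom == points$chrom[1]]) ||
      dplyr::n_distinct(points$chrom) > 1 &&
      any(unlist(tapply(points$pos, points$chrom, is.unsorted)))) {
    abort("`points` must be sorted by (chrom, pos); sort before profiling.")
  }
  if (window_size %% step != 0) abort("`step` must divide `window_size`.")
  ratio <- window_size %/% step

  per_chrom <- function(chrom, df) {
    L <- if (!is.null(chrom_lengths)) unname(chrom_lengths[chrom]) else max(df$pos)
    starts <- seq(1, max(1, L - window_size + 1), by = step)
    n_bins <- length(starts) + ratio - 1L   # step-sized bins covering [1, L]
    bin <- pmin(((df$pos - 1) %/% step) + 1L, n_bins)
    ok <- !is.na(df$delta)
    acc <- function(v) {
      s <- rep(0, n_bins)
      t <- tapply(v[ok], bin[ok], sum)
      s[as.integer(names(t))] <- t
      # rolling sum of `ratio` consecutive step-bins = one window
      cs <- c(0, cumsum(s))
      cs[seq_along(starts) + ratio] - cs[seq_along(starts)]
    }
    n <- acc(rep(1, nrow(df)))
    tibble::tibble(
      chrom = chrom,
      start = starts,
      end = starts + window_size - 1,
      n_snps = as.integer(n),
      index_mut = ifelse(n > 0, acc(df$index_mut) / n, NA_real_),
      index_wt = ifelse(n > 0, acc(df$index_wt) / n, NA_real_),
      delta = ifelse(n > 0, acc(df$delta) / n, NA_real_),
      missing = n < min_snps
    )
  }

  out <- dplyr::bind_rows(lapply(
    split(points, points$chrom),
    function(df) per_chrom(df$chrom[1], df)
  ))
  structure(
    dplyr::arrange(out, .data$chrom, .data$start),
    class = c("bsa_profile", class(out)),
    window_size = window_size, step = step, min_snps = min_snps
  )
}

#' Monte-Carlo confidence envelope for the null delta SNP-index
#'
#' Simulates the no-linkage null at window scale: at each site the
#' mutant-parent allele frequency of a bulk is the realized frequency among
#' `2 x bulk_size` freely segregating F2 chromosomes (each P1 with
#' probability 1/2), read counts are binomial at the site's depth, and a
#' window's null delta is the mean over its simulated sites. The envelope is
#' the requested upper percentiles of |delta| per window SNP count, so a
#' profile window is compared against an envelope matched to its own
#' `n_snps`.
#'
#' @param bulk_size_mut,bulk_size_wt Individuals per bulk.
#' @param mean_depth Mean read depth per site per bulk.
#' @param n_snps Integer vector of window SNP counts to tabulate (one
#'   envelope row each).
#' @param n_sims Simulations per row (default 10000; fewer than 100 warns).
#' @param percentiles Upper percentiles of |delta| (default `c(95, 99)`).
#' @param depth_model `"poisson"` or `"fixed"`.
#' @param seed Optional integer seed (stored on the result).
#' @return A `bsa_envelope` tibble: `n_snps`, one `q<p>` column per
#'   percentile, `n_sims`.
#' @examples
#' null_envelope(30, 30, 30, n_snps = c(5, 20), n_sims = 500, seed = 1)
#' @export
null_envelope <- function(bulk_size_mut, bulk_size_wt, mean_depth,
                          n_snps, n_sims = 10000, percentiles = c(95, 99),
                          depth_model = c("poisson", "fixed"), seed = NULL) {
  depth_model <- match.arg(depth_model)
  bulk_size_mut <- check_count(bulk_size_mut, "bulk_size_mut", 1)
  bulk_size_wt <- check_count(bulk_size_wt, "bulk_size_wt", 1)
  if (mean_depth <= 0) abort("`mean_depth` must be positive.")
  if (n_sims < 100) warn("Fewer than 100 simulations: envelope percentiles are unstable.")
  n_snps <- sort(unique(as.integer(n_snps)))
  n_snps <- n_snps[n_snps >= 1]
  if (length(n_snps) == 0) abort("`n_snps` must contain positive counts.")
  local_seed(seed)

  rows <- lapply(n_snps, function(m) {
    deltas <- sim_null_window_delta(m, n_sims, bulk_size_mut, bulk_size_wt,
                                    mean_depth, depth_model)
    qs <- quantile(abs(deltas), probs = percentiles / 100, na.rm = TRUE)
    tibble::as_tibble(c(
      list(n_snps = m),
      setNames(as.list(unname(qs)), paste0("q", percentiles))
    ))
  })
  out <- dplyr::bind_rows(rows)
  out$n_sims <- n_sims
  structure(out, class = c("bsa_envelope", class(out)),
            percentiles = percentiles, seed = seed,
            bulk_size_mut = bulk_size_mut, bulk_size_wt = bulk_size_wt,
            mean_depth = mean_depth, depth_model = depth_model)
}

# one null window mean delta per simulation: m sites, vectorized over sims
sim_null_window_delta <- function(m, n_sims, bulk_size_mut, bulk_size_wt,
                                  mean_depth, depth_model) {
  n <- m * n_sims
  one_bulk <- function(size) {
    freq <- rbinom(n, 2L * size, 0.5) / (2 * size)
    depth <- switch(depth_model,
      poisson = rpois(n, mean_depth),
      fixed = rep(as.integer(round(mean_depth)), n)
    )
    ifelse(depth > 0, rbinom(n, depth, freq) / depth, NA_real_)
  }
  delta <- one_bulk(bulk_size_mut) - one_bulk(bulk_size_wt)
  rowMeans(matrix(delta, n_sims, m), na.rm = TRUE)
}

#' Call candidate regions from a profile and a null envelope
#'
#' Flags non-missing windows whose mean delta SNP-index exceeds the
#' envelope percentile matched to the window's SNP count, then merges
#' overlapping or book-ended significant windows into candidate regions,
#' each reporting its peak window.
#'
#' @param profile A [window_profile()] result.
#' @param envelope A [null_envelope()] result covering every `n_snps`
#'   present in the profile's non-missing windows (missing counts fall back
#'   to the nearest tabulated count, with a warning).
#' @param level Confidence level: one of the envelope's percentiles
#'   (default 99).
#' @return A `bsa_regions` tibble: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_start`, `peak_end`, `peak_pos` (peak-window midpoint),
#'   `peak_delta`, `level`.
#' @export
call_regions <- function(profile, envelope, level = 99) {
  qcol <- paste0("q", level)
  if (!qcol %in% names(envelope)) {
    abort(sprintf("Envelope has no %s%% percentile column.", level))
  }
  prof <- profile[!profile$missing & !is.na(profile$delta), , drop = FALSE]
  if (nrow(prof) == 0) return(empty_regions(level))

  idx <- match(prof$n_snps, envelope$n_snps)
  if (anyNA(idx)) {
    warn("Some window SNP counts are not tabulated in the envelope; using nearest.")
    near <- vapply(prof$n_snps[is.na(idx)], function(m) {
      which.min(abs(envelope$n_snps - m))
    }, integer(1))
    idx[is.na(idx)] <- near
  }
  prof$threshold <- envelope[[qcol]][idx]
  sig <- prof[prof$delta > prof$threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty_regions(level))

  sig <- dplyr::arrange(sig, .data$chrom, .data$start)
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                 sig$start[-1] > sig$end[-nrow(sig)] + 1)
  sig$run <- cumsum(new_run)
  out <- dplyr::group_by(sig, .data$run)
  out <- dplyr::summarise(
    out,
    chrom = dplyr::first(.data$chrom),
    peak_start = .data$start[which.max(.data$delta)],
    peak_end = .data$end[which.max(.data$delta)],
    peak_delta = max(.data$delta),
    start = min(.data$start), end = max(.data$end),
    n_windows = dplyr::n(),
    .groups = "drop"
  )
  out$peak_pos <- (out$peak_start + out$peak_end) / 2
  out$level <- level
  out <- dplyr::select(out, -"run")
  structure(out, class = c("bsa_regions", class(out)))
}

empty_regions <- function(level) {
  structure(
    tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      n_windows = integer(), peak_start = numeric(), peak_end = numeric(),
      peak_delta = numeric(), peak_pos = numeric(), level = numeric()
    ),
    class = c("bsa_regions", "tbl_df", "tbl", "data.frame")
  )
}

#' One-call bulked-segregant scan
#'
#' Convenience wrapper chaining [snp_index_points()], [window_profile()],
#' [null_envelope()] and [call_regions()] with the motivating study's
#' defaults (200-kb windows, 20-kb step, 99% confidence level).
#'
#' @inheritParams window_profile
#' @inheritParams null_envelope
#' @param bulk_counts Long bulk-counts tibble.
#' @param level Confidence level for region calling.
#' @return List with `points`, `profile`, `envelope`, `regions`.
#' @export
bsa_scan <- function(bulk_counts, bulk_size_mut = 30, bulk_size_wt = 30,
                     window_size = 200000, step = 20000, min_snps = 3,
                     level = 99, n_sims = 10000, depth_model = "poisson",
                     chrom_lengths = NULL, seed = NULL) {
  points <- snp_index_points(bulk_counts)
  profile <- window_profile(points, window_size = window_size, step = step,
                            min_snps = min_snps, chrom_lengths = chrom_lengths)
  counts <- unique(profile$n_snps[!profile$missing])
  mean_depth <- mean(c(points$depth_mut, points$depth_wt), na.rm = TRUE)
  envelope <- null_envelope(
    bulk_size_mut, bulk_size_wt, mean_depth,
    n_snps = counts, n_sims = n_sims,
    depth_model = depth_model, seed = seed
  )
  regions <- call_regions(profile, envelope, level = level)
  list(points = points, profile = profile, envelope = envelope,
       regions = regions)
}
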