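#' Per-column diversity of a gapped multiple alignment
#'
#' For each alignment column, the diversity is the proportion of unordered
#' row pairs whose characters differ, with the gap character treated as a
#' distinct fifth state (a deletion is a real sequence difference). `N`
#' characters are excluded from pairing entirely; a column with fewer than
#' two non-`N` rows yields `NA`.
#'
#' @param alignment Tibble with columns `label` and `sequence` (equal gapped
#'   lengths, alphabet `A C G T N -`), e.g. from
#'   [simulate_promoter_family()]`$alignment` or [read_alignment_fasta()].
#' @return Numeric vector of per-column diversities in `[0, 1]`.
#' @examples
#' aln <- tibble::tibble(label = c("a", "b", "c", "d"),
#'                       sequence = c("AAT", "AAT", "TAT", "TA-"))
#' column_diversity(aln)
#' @export
column_diversity <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2) abort("Need at least two alignment rows.")
  states <- c("A", "C", "G", "T", "-")
  counts <- vapply(states, function(s) colSums(m == s), numeric(ncol(m)))
  if (ncol(m) == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, states))
  eff <- rowSums(counts)                       # rows minus Ns per column
  same_pairs <- rowSums(counts * (counts - 1) / 2)
  total_pairs <- eff * (eff - 1) / 2
  ifelse(total_pairs > 0, 1 - same_pairs / total_pairs, NA_real_)
}

alignment_matrix <- function(alignment) {
  if (!all(c("label", "sequence") %in% names(alignment))) {
    abort("`alignment` must have columns `label` and `sequence`.")
  }
  lens <- nchar(alignment$sequence)
  if (length(unique(lens)) != 1) {
    abort("All alignment rows must have the same gapped length.")
  }
  m <- do.call(rbind, strsplit(toupper(alignment$sequence), ""))
  bad <- !m %in% c("A", "C", "G", "T", "N", "-")
  if (any(bad)) abort("Alignment alphabet is {A, C, G, T, N, -}.")
  rownames(m) <- alignment$label
  m
}

# alignment column index for each ungapped position of the reference row
map_ref_to_aln <- function(alignment, reference) {
  m <- alignment_matrix(alignment)
  if (!reference %in% rownames(m)) {
    abort(sprintf("Reference row '%s' not found in the alignment.", reference))
  }
  which(m[reference, ] != "-")
}

#' Windowed diversity profile in reference coordinates
#'
#' Averages per-column diversity over sliding windows defined on the
#' ungapped coordinates of a designated reference row (50-bp windows every
#' 10 bp in the motivating analysis), so the profile shares one axis with
#' features annotated on the reference sequence. Columns where the
#' reference carries a gap map to no reference position and are skipped.
#' For reference length `L >= window` the profile has
#' `floor((L - window)/step) + 1` windows; shorter sequences collapse to a
#' single whole-sequence window with a warning.
#'
#' @inheritParams column_diversity
#' @param reference Label of the reference row; default the first row.
#' @param window Window size in reference bp (default 50).
#' @param step Step in reference bp (default 10).
#' @return A `conservation_profile` tibble: `start`, `end` (1-based
#'   inclusive reference coordinates), `diversity`, with `window`, `step`,
#'   `reference` and the per-position diversity vector as attributes.
#' @export
window_diversity <- function(alignment, reference = NULL, window = 50,
                             step = 10) {
  reference <- reference %||% alignment$label[1]
  cols <- map_ref_to_aln(alignment, reference)
  div <- column_diversity(alignment)[cols]    # one value per reference bp
  L <- length(div)
  if (L < window) {
    warn(sprintf(
      "Reference length %d is shorter than the window (%d); using one window.",
      L, window
    ))
    starts <- 1L
    vals <- mean(div, na.rm = TRUE)
    ends <- L
  } else {
    starts <- seq(1L, L - window + 1L, by = step)
    cs <- c(0, cumsum(ifelse(is.na(div), 0, div)))
    cn <- c(0, cumsum(!is.na(div)))
    sums <- cs[starts + window] - cs[starts]
    ns <- cn[starts + window] - cn[starts]
    vals <- ifelse(ns > 0, sums / ns, NA_real_)
    ends <- starts + window - 1L
  }
  structure(
    tibble::tibble(start = starts, end = ends, diversity = vals),
    class = c("conservation_profile", "tbl_df", "tbl", "data.frame"),
    window = window, step = step, reference = reference,
    ref_length = L, per_position = div
  )
}

#' Call conserved regions from a diversity profile
#'
#' Conserved regions are maximal runs of windows whose mean diversity lies
#' strictly below the threshold (0.3 in the motivating analysis); the
#' overlapping window spans of a run are merged into one reference-space
#' region.
#'
#' @param profile A [window_diversity()] result.
#' @param threshold Diversity threshold (default 0.3).
#' @return A tibble `start`, `end`, `n_windows`, `mean_diversity` (mean of
#'   the member windows), sorted by position.
#' @export
call_conserved <- function(profile, threshold = 0.3) {
  low <- !is.na(profile$diversity) & profile$diversity < threshold
  if (!any(low)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_windows = integer(), mean_diversity = numeric()))
  }
  runs <- rle(low)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1
  keep <- which(runs$values)
  tibble::tibble(
    start = profile$start[run_start[keep]],
    end = profile$end[run_end[keep]],
    n_windows = runs$lengths[keep],
    mean_diversity = vapply(keep, function(k) {
      mean(profile$diversity[run_start[k]:run_end[k]])
    }, numeric(1))
  )
}

#' Overlap of a structural variant with conserved promoter regions
#'
#' Given a reference-space interval (for example a promoter deletion), calls
#' the conserved regions of the alignment and reports how many bp of the
#' interval fall inside each, plus the overall fraction of the interval
#' covered by conserved sequence. Because both the profile and the interval
#' live in reference (ungapped) coordinates, the reference row's gap
#' structure is handled once, inside the windowing.
#'
#' @inheritParams window_diversity
#' @param interval `c(start, end)` (1-based inclusive reference bp) or a
#'   data frame with `start`/`end`.
#' @param threshold Diversity threshold for [call_conserved()].
#' @return A `sv_overlap` tibble: one row per conserved region with
#'   `start`, `end`, `mean_diversity`, `overlap_bp`; attributes
#'   `interval` and `fraction_covered` (total overlap / interval length).
#' @export
sv_overlap <- function(alignment, interval, reference = NULL, window = 50,
                       step = 10, threshold = 0.3) {
  if (is.numeric(interval) && length(interval) == 2) {
    iv <- list(start = interval[1], end = interval[2])
  } else {
    iv <- list(start = interval$start[1], end = interval$end[1])
  }
  if (iv$start > iv$end) abort("Interval start exceeds end.")
  profile <- window_diversity(alignment, reference = reference,
                              window = window, step = step)
  L <- attr(profile, "ref_length")
  if (iv$start < 1 || iv$end > L) {
    abort(sprintf("Interval [%g, %g] is outside the reference (length %d).",
                  iv$start, iv$end, L))
  }
  regions <- call_conserved(profile, threshold = threshold)
  overlap <- pmax(0, pmin(regions$end, iv$end) - pmax(regions$start, iv$start) + 1)
  out <- dplyr::mutate(regions, overlap_bp = overlap)
  structure(
    out,
    class = c("sv_overlap", class(regions)),
    interval = c(iv$start, iv$end),
    fraction_covered = sum(overlap) / (iv$end - iv$start + 1)
  )
}
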