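#' Relative expression by the 2^-ddCt method
#'
#' Computes relative expression fold changes from qRT-PCR cycle-threshold
#' values with one or more reference genes. Per record,
#' `dCt = target Ct - mean(reference Cts)`; relative to the calibrator,
#' `ddCt = dCt - dCt_calibrator` and the fold change is `2^-ddCt`.
#' Averaging reference Cts arithmetically is equivalent to normalizing by
#' the geometric mean of the reference genes' linear abundances.
#'
#' @param data Tibble with one row per sample: an identifier column, a
#'   target-Ct column and one column per reference gene.
#' @param target Name of the target-Ct column (default `"ct_target"`).
#' @param refs Tidyselect for the reference-Ct columns (default columns
#'   starting with `"ct_ref"`).
#' @param calibrator Identifier of the calibrator row, matched against
#'   `id_col`; or a logical vector/column name flagging it.
#' @param id_col Identifier column name (default `"sample"`).
#' @return The input with `dct`, `ddct` and `fold_change` columns appended.
#' @examples
#' d <- tibble::tibble(
#'   sample = c("wt", "mut"),
#'   ct_target = c(25, 23),
#'   ct_ref1 = c(20, 20), ct_ref2 = c(22, 22), ct_ref3 = c(24, 24)
#' )
#' ddct_fold_change(d, calibrator = "wt")
#' @export
ddct_fold_change <- function(data, target = "ct_target",
                             refs = dplyr::starts_with("ct_ref"),
                             calibrator, id_col = "sample") {
  ref_ct <- dplyr::select(data, {{ refs }})
  if (ncol(ref_ct) < 1) abort("At least one reference-gene Ct column is required.")
  ct_t <- data[[target]]
  if (any(!is.finite(ct_t)) || any(ct_t <= 0)) {
    abort("Target Ct values must be finite and positive.")
  }
  refm <- as.matrix(ref_ct)
  if (any(!is.finite(refm)) || any(refm <= 0)) {
    abort("Reference Ct values must be finite and positive.")
  }
  dct <- ct_t - rowMeans(refm)

  if (is.character(calibrator) && length(calibrator) == 1 &&
      calibrator %in% data[[id_col]]) {
    cal <- data[[id_col]] == calibrator
  } else if (is.logical(calibrator) && length(calibrator) == nrow(data)) {
    cal <- calibrator
  } else {
    abort("`calibrator` must name a row of `id_col` or be a logical vector.")
  }
  if (sum(cal) < 1) abort("No calibrator row found.")
  dct_cal <- mean(dct[cal])
  dplyr::mutate(data, dct = dct, ddct = dct - dct_cal,
                fold_change = 2^-(dct - dct_cal))
}

#' Dual-luciferase LUC/REN ratios with group summaries
#'
#' Normalizes firefly luciferase signal by the Renilla internal control per
#' sample and summarizes replicate groups by mean and sample (n-1) standard
#' deviation, the usual "mean +/- SD of n = 3 replicates" presentation.
#'
#' @param data Tibble with firefly and Renilla signal columns.
#' @param firefly,renilla Column names (defaults `"firefly"`, `"renilla"`).
#' @param group Optional grouping column name for the summary.
#' @return List with `samples` (input plus `ratio`) and `summary` (per
#'   group: `n`, `mean_ratio`, `sd_ratio`; one overall row when `group` is
#'   NULL).
#' @examples
#' d <- tibble::tibble(construct = "p35S", firefly = c(2, 4, 6),
#'                     renilla = c(2, 2, 2))
#' luc_ren_ratio(d, group = "construct")$summary
#' @export
luc_ren_ratio <- function(data, firefly = "firefly", renilla = "renilla",
                          group = NULL) {
  ff <- data[[firefly]]
  rn <- data[[renilla]]
  if (any(!is.finite(rn)) || any(rn <= 0)) {
    abort("Renilla signal must be finite and strictly positive.")
  }
  samples <- dplyr::mutate(data, ratio = ff / rn)
  grouped <- if (is.null(group)) samples
  else dplyr::group_by(samples, dplyr::across(dplyr::all_of(group)))
  summary <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean_ratio = mean(.data$ratio),
    sd_ratio = sd(.data$ratio),
    .groups = "drop"
  )
  list(samples = samples, summary = summary)
}
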