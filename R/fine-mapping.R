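#' Infer a candidate interval from a recombinant panel
#'
#' Under a fully penetrant monogenic recessive model (mutant allele from
#' P1), a marker position is excluded as the causal location whenever any
#' individual contradicts the model there: a mutant individual that is not
#' P1-homozygous, or — when the panel consists of homozygous (fixed) lines —
#' a wild-type individual that is P1-homozygous. Missing calls are
#' uninformative and never exclude. The candidate interval is the contiguous
#' span covering every non-excluded marker, reported with its flanking
#' excluded markers as bounds (falling back to the first/last marker when no
#' exclusion flanks a side). Excluded markers strictly inside the span —
#' islands created by double recombinants — are counted in
#' `n_interior_excluded` but never clip the span, so the causal position of
#' an error-free panel always lies inside.
#'
#' Wild-type heterozygotes carry the recessive allele without showing the
#' phenotype, so in a segregating panel they exclude nothing; declaring
#' `homozygous_lines = TRUE` (e.g. BCnSm fixed recombinant lines) makes
#' wild-type P1-homozygosity exclusionary.
#'
#' @param panel Wide tibble: one row per individual with a `phenotype`
#'   column (`"mutant"`/`"wildtype"`) and one column per marker holding
#'   calls in `{"P1", "H", "P2", NA}` (aliases `"A"`/`"B"`/`"-"` accepted).
#' @param markers Tibble `marker`, `chrom`, `pos` mapping marker column
#'   names to sorted genomic positions.
#' @param homozygous_lines Is the panel composed of homozygous recombinant
#'   lines? Default `FALSE`.
#' @return A `candidate_interval` one-row tibble: `chrom`, `left`, `right`
#'   (positions of the flanking markers), `left_marker`, `right_marker`,
#'   `n_markers_in` (non-excluded markers inside).
#' @examples
#' markers <- tibble::tibble(marker = c("m1", "m2", "m3"),
#'                           chrom = "c6", pos = c(100, 200, 300))
#' panel <- tibble::tibble(
#'   phenotype = c("mutant", "mutant"),
#'   m1 = c("H", "P1"), m2 = c("P1", "P1"), m3 = c("P1", "H")
#' )
#' infer_interval(panel, markers)
#' @export
infer_interval <- function(panel, markers, homozygous_lines = FALSE) {
  check_panel(panel, markers)
  markers <- dplyr::arrange(markers, .data$pos)
  calls <- normalize_calls(panel, markers$marker)
  pheno <- panel$phenotype

  excluded <- vapply(seq_len(nrow(markers)), function(j) {
    g <- calls[, j]
    bad_mut <- pheno == "mutant" & !is.na(g) & g != "P1"
    bad_wt <- homozygous_lines & pheno == "wildtype" & !is.na(g) & g == "P1"
    any(bad_mut | bad_wt)
  }, logical(1))

  if (all(excluded)) {
    contradicting <- which(vapply(seq_len(nrow(calls)), function(i) {
      g <- calls[i, ]
      if (pheno[i] == "mutant") any(!is.na(g) & g != "P1")
      else homozygous_lines && any(!is.na(g) & g == "P1")
    }, logical(1)))
    abort(paste0(
      "Every marker position is excluded; the panel is inconsistent with a ",
      "monogenic recessive model. Contradicting individuals (rows): ",
      paste(contradicting, collapse = ", ")
    ))
  }

  # the candidate span covers every non-excluded position; interior
  # excluded markers (islands from double recombinants) stay inside it
  open <- which(!excluded)
  i0 <- min(open); i1 <- max(open)
  left_idx <- if (i0 > 1) i0 - 1L else 1L
  right_idx <- if (i1 < nrow(markers)) i1 + 1L else nrow(markers)
  structure(
    tibble::tibble(
      chrom = markers$chrom[1],
      left = markers$pos[left_idx],
      right = markers$pos[right_idx],
      left_marker = markers$marker[left_idx],
      right_marker = markers$marker[right_idx],
      n_markers_in = length(open),
      n_interior_excluded = (i1 - i0 + 1L) - length(open)
    ),
    class = c("candidate_interval", "tbl_df", "tbl", "data.frame")
  )
}

check_panel <- function(panel, markers) {
  if (!"phenotype" %in% names(panel)) abort("`panel` needs a `phenotype` column.")
  if (nrow(panel) < 1) abort("`panel` must contain at least one individual.")
  if (!all(panel$phenotype %in% c("mutant", "wildtype"))) {
    abort("Phenotypes must be 'mutant' or 'wildtype'.")
  }
  if (!all(markers$marker %in% names(panel))) {
    abort("Every marker in `markers` must be a column of `panel`.")
  }
  if (anyDuplicated(markers$pos)) abort("Marker positions must be distinct.")
  invisible(TRUE)
}

normalize_calls <- function(panel, marker_names) {
  m <- as.matrix(panel[, marker_names, drop = FALSE])
  m[m %in% c("-", "", "NA")] <- NA
  m[m == "A"] <- "P1"
  m[m == "B"] <- "P2"
  bad <- !is.na(m) & !m %in% c("P1", "H", "P2")
  if (any(bad)) abort("Genotype calls must be in {P1/A, H, P2/B, -/NA}.")
  m
}

#' Marker-phenotype co-segregation
#'
#' A marker co-segregates perfectly with a recessive trait when every mutant
#' individual is P1-homozygous and every wild-type individual is not.
#' Missing calls are uninformative.
#'
#' @param calls Genotype calls in `{"P1", "H", "P2", NA}` (aliases as in
#'   [infer_interval()]).
#' @param phenotypes Matching vector of `"mutant"`/`"wildtype"`.
#' @return Tibble `perfect` (logical), `mismatches`, `n_informative`.
#' @examples
#' cosegregation(c("P1", "P1", "H"), c("mutant", "mutant", "wildtype"))
#' @export
cosegregation <- function(calls, phenotypes) {
  if (length(calls) != length(phenotypes)) {
    abort("`calls` and `phenotypes` must have equal length.")
  }
  g <- normalize_calls(tibble::tibble(x = as.character(calls)), "x")[, 1]
  informative <- !is.na(g)
  mismatch <- informative &
    ((phenotypes == "mutant" & g != "P1") |
       (phenotypes == "wildtype" & g == "P1"))
  tibble::tibble(
    perfect = !any(mismatch),
    mismatches = sum(mismatch),
    n_informative = sum(informative)
  )
}

#' Physical length of a candidate interval
#'
#' Published interval sizes mix two conventions: the span between two
#' flanking markers is usually `right - left` (flank-difference), while a
#' feature such as a deletion given by its first and last base measures
#' `right - left + 1` (inclusive). Both are explicit here.
#'
#' @param interval A `candidate_interval`, or any data frame with `left`
#'   and `right` columns, or a numeric `c(left, right)`.
#' @param convention `"flank"` (difference) or `"inclusive"`.
#' @return Tibble `left`, `right`, `convention`, `bp`, `kb` (1 d.p.).
#' @examples
#' interval_length(c(37945500, 38129705), "flank")      # ~184.2 kb
#' interval_length(c(38062128, 38062543), "inclusive")  # 416 bp
#' @export
interval_length <- function(interval, convention = c("flank", "inclusive")) {
  convention <- match.arg(convention)
  if (is.numeric(interval) && length(interval) == 2) {
    left <- interval[1]; right <- interval[2]
  } else {
    left <- interval$left; right <- interval$right
  }
  if (any(left > right)) abort("Interval left bound exceeds right bound.")
  bp <- switch(convention, flank = right - left, inclusive = right - left + 1)
  tibble::tibble(
    left = left, right = right, convention = convention,
    bp = bp, kb = round(bp / 1000, 1)
  )
}

#' Genes overlapping a candidate interval
#'
#' Returns the annotated genes whose body overlaps the interval by at least
#' one bp, strand-agnostic, using 1-based inclusive coordinates on both
#' sides.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, ...), e.g.
#'   from [read_gff3_genes()].
#' @param interval A `candidate_interval` or list/tibble with `chrom`,
#'   `left`, `right`.
#' @return The overlapping rows of `genes`; `nrow()` is the gene count.
#' @export
genes_in_interval <- function(genes, interval) {
  chrom <- interval$chrom[1]
  if (nrow(genes) > 0 && !chrom %in% genes$chrom) {
    abort(sprintf("Chromosome '%s' is absent from the annotation.", chrom))
  }
  genes[genes$chrom == chrom &
          genes$start <= interval$right[1] &
          genes$end >= interval$left[1], , drop = FALSE]
}

#' Simulate a panel of homozygous recombinant lines
#'
#' Generates fixed (homozygous) recombinant lines around a known causal
#' position, the structure used for final interval narrowing: each line is a
#' single recombination mosaic of P1 and P2 homozygous blocks, and its
#' phenotype follows the genotype at the causal position. A companion for
#' testing [infer_interval()] on ground truth.
#'
#' @param n_lines Number of lines.
#' @param markers Tibble `marker`, `chrom`, `pos` (sorted).
#' @param causal_position Causal bp (need not be a marker).
#' @param cm_per_mb,seed As in [simulate_f2()].
#' @return List `panel` (wide tibble with `line`, `phenotype`, marker
#'   columns) and `markers`.
#' @export
simulate_recombinant_lines <- function(n_lines, markers, causal_position,
                                       cm_per_mb = 4, seed = NULL) {
  n_lines <- check_count(n_lines, "n_lines", 1)
  local_seed(seed)
  pos <- sort(unique(c(markers$pos, causal_position)))
  causal_idx <- match(causal_position, pos)
  marker_idx <- match(markers$pos, pos)
  d <- diff(pos) / 1e6 * cm_per_mb / 100
  r <- 0.5 * (1 - exp(-2 * d))
  hap <- sim_gametes(n_lines, r)            # one mosaic, then fixed by selfing
  calls <- matrix(c("P2", "P1")[hap[, marker_idx, drop = FALSE] + 1L],
                  nrow = n_lines)
  colnames(calls) <- markers$marker
  panel <- dplyr::bind_cols(
    tibble::tibble(
      line = sprintf("L%03d", seq_len(n_lines)),
      phenotype = ifelse(hap[, causal_idx] == 1L, "mutant", "wildtype")
    ),
    tibble::as_tibble(calls)
  )
  list(panel = panel, markers = markers)
}
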