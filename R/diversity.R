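#' Per-site nucleotide diversity
#'
#' For a biallelic site with `ref_count` and `alt_count` sampled haplotypes,
#' pi is the fraction of unordered haplotype pairs that differ:
#' `ref_count * alt_count / choose(n, 2)`, i.e. the mean pairwise difference
#' at the site. Vectorized; returns `NA` where fewer than two haplotypes
#' were observed.
#'
#' @param ref_count,alt_count Haplotype counts of the two alleles.
#' @return Numeric vector of per-site pi values in `[0, 1]`.
#' @examples
#' site_pi(2, 2)   # 4/6
#' site_pi(1, 3)   # 3/6
#' @export
site_pi <- function(ref_count, alt_count) {
  n <- ref_count + alt_count
  out <- ifelse(n >= 2, ref_count * alt_count / choose(n, 2), NA_real_)
  as.numeric(out)
}

#' Nucleotide diversity of a genomic region
#'
#' Sums [site_pi()] over the variant sites falling inside the region and
#' divides by the region length (the conventional windowed-pi definition, in
#' which monomorphic positions contribute zero through the denominator).
#' Sites with missing genotypes use the haplotype count observed at that
#' site. Set `denominator = "sites"` to average over variant sites only.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ac` (alternate
#'   allele count) and `an` (observed haplotypes at the site).
#' @param chrom,start,end Region coordinates (1-based inclusive).
#' @param denominator `"region"` (default, per-bp over the full region
#'   length) or `"sites"` (per variant site).
#' @return A single pi value (`NA` for an empty region under `"sites"` with
#'   no sites it is 0 under `"region"`).
#' @examples
#' v <- tibble::tibble(chrom = "c1", pos = 50, ac = 2, an = 4)
#' region_pi(v, "c1", 1, 100)   # 0.6667 / 100
#' @export
region_pi <- function(variants, chrom, start, end,
                      denominator = c("region", "sites")) {
  denominator <- match.arg(denominator)
  len <- end - start + 1
  if (len <= 0) return(NA_real_)
  inside <- variants$chrom == chrom & variants$pos >= start & variants$pos <= end
  v <- variants[inside, , drop = FALSE]
  sp <- site_pi(v$an - v$ac, v$ac)
  sp <- sp[!is.na(sp)]
  if (denominator == "region") sum(sp) / len
  else if (length(sp) == 0) NA_real_ else mean(sp)
}

#' Upstream / body / downstream regions for each gene
#'
#' Builds the strand-aware region set used for per-gene diversity scans: for
#' a + strand gene `[s, e]` the upstream flank is `[s - flank, s - 1]` and
#' the downstream flank `[e + 1, e + flank]`; mirrored for - strand genes.
#' Flanks are truncated at position 1 and, when `chrom_lengths` is supplied,
#' at the chromosome end; a flank truncated to nothing is dropped.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`; anything else is an error).
#' @param flank Flank length in bp (default 3000).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Tibble `gene_id`, `region` (`upstream`/`body`/`downstream`),
#'   `chrom`, `start`, `end`.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "c1", start = 5000,
#'                     end = 7000, strand = "+")
#' gene_regions(g)
#' @export
gene_regions <- function(genes, flank = 3000, chrom_lengths = NULL) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    abort(paste("`genes` must have columns:", paste(req, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("Every gene must have strand '+' or '-'; missing strand is not allowed.")
  }
  flank <- check_count(flank, "flank", 1)

  up <- dplyr::mutate(
    genes,
    region = "upstream",
    rs = ifelse(.data$strand == "+", .data$start - flank, .data$end + 1),
    re = ifelse(.data$strand == "+", .data$start - 1, .data$end + flank)
  )
  dn <- dplyr::mutate(
    genes,
    region = "downstream",
    rs = ifelse(.data$strand == "+", .data$end + 1, .data$start - flank),
    re = ifelse(.data$strand == "+", .data$end + flank, .data$start - 1)
  )
  bd <- dplyr::mutate(genes, region = "body", rs = .data$start, re = .data$end)

  out <- dplyr::bind_rows(up, bd, dn)
  out$rs <- pmax(out$rs, 1)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[out$chrom])
    if (any(is.na(lim))) abort("`chrom_lengths` is missing some chromosomes.")
    out$re <- pmin(out$re, lim)
  }
  out <- out[out$re >= out$rs, , drop = FALSE]
  out <- dplyr::transmute(
    out, gene_id = .data$gene_id, region = .data$region,
    chrom = .data$chrom, start = .data$rs, end = .data$re
  )
  dplyr::arrange(out, .data$gene_id,
                 match(.data$region, c("upstream", "body", "downstream")))
}

#' Per-gene, per-region nucleotide diversity summary
#'
#' Applies [region_pi()] to every row of a [gene_regions()] table, giving
#' the genome-wide per-region-class pi distribution from which focal genes
#' can be ranked.
#'
#' @param variants Variant tibble as for [region_pi()].
#' @param regions Output of [gene_regions()].
#' @inheritParams region_pi
#' @return Tibble `gene_id`, `region`, `chrom`, `start`, `end`, `length`,
#'   `n_sites`, `pi`, of class `pi_summary`.
#' @export
pi_summary <- function(variants, regions, denominator = c("region", "sites")) {
  denominator <- match.arg(denominator)
  out <- regions
  out$length <- out$end - out$start + 1
  out$n_sites <- purrr::pmap_int(
    regions[c("chrom", "start", "end")],
    function(chrom, start, end) {
      sum(variants$chrom == chrom & variants$pos >= start & variants$pos <= end)
    }
  )
  out$pi <- purrr::pmap_dbl(
    regions[c("chrom", "start", "end")],
    function(chrom, start, end) {
      region_pi(variants, chrom, start, end, denominator = denominator)
    }
  )
  class(out) <- c("pi_summary", class(out))
  out
}

#' Percentile rank of a focal gene's diversity within a region class
#'
#' Reports the percentage of *other* genes whose pi in the same region class
#' is strictly greater than the focal gene's — the sense in which a strongly
#' conserved promoter has lower diversity "than 93.8% of all other genes".
#'
#' @param summary A [pi_summary()] tibble.
#' @param gene_id Focal gene identifier.
#' @param region Region class: `"upstream"`, `"body"` or `"downstream"`.
#' @return A one-row tibble `gene_id`, `region`, `pi`, `n_other`,
#'   `percent_greater`.
#' @export
rank_gene <- function(summary, gene_id, region) {
  sub <- summary[summary$region == region & !is.na(summary$pi), , drop = FALSE]
  focal <- sub[sub$gene_id == gene_id, , drop = FALSE]
  if (nrow(focal) == 0) {
    abort(sprintf("Gene '%s' has no %s pi value in the summary.", gene_id, region))
  }
  others <- sub$pi[sub$gene_id != gene_id]
  if (length(others) < 1) abort("Need at least one other gene to rank against.")
  tibble::tibble(
    gene_id = gene_id, region = region, pi = focal$pi[1],
    n_other = length(others),
    percent_greater = 100 * mean(others > focal$pi[1])
  )
}
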