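#' Simulate a toy variome with region-specific variant densities
#'
#' Places `n_genes` genes (alternating strands) on one synthetic chromosome
#' with enough spacing that the 3-kb flanks never overlap, then scatters
#' biallelic variant sites over each gene's upstream flank, body and
#' downstream flank at configurable per-bp densities. Each variant's
#' alternate-allele count is uniform on `{1, ..., n_samples - 1}` and
#' assigned to a random subset of the haploid sample panel. The generator
#' records, per gene and region, the expected nucleotide diversity under its
#' own model: with the uniform allele-count distribution the expected
#' per-site pi is `(n + 1) / (3 (n - 1))`, so the expected per-bp region pi
#' is the variant density times that factor.
#'
#' @param n_genes Number of genes (default 100).
#' @param flank_length Upstream/downstream flank in bp (default 3000).
#' @param body_length_range Min/max gene-body length in bp, drawn uniformly
#'   (default `c(1000, 5000)`).
#' @param density_upstream,density_body,density_downstream Variants per bp
#'   in each region class (defaults 0.01 / 0.005 / 0.01).
#' @param n_samples Number of haploid samples (haplotypes), >= 2; default 20.
#' @param chrom Chromosome name.
#' @param seed Optional integer seed.
#'
#' @return A `variome_sim`: list with `variants` (tibble `chrom`, `pos`,
#'   `ref`, `alt`, `ac`, `an`), `genotypes` (0/1 integer matrix, sites x
#'   samples), `genes` (tibble `gene_id`, `chrom`, `start`, `end`,
#'   `strand`), `truth` (tibble `gene_id`, `region`, `length`,
#'   `expected_pi`), `n_samples`, `chrom_length`, `flank_length`.
#'
#' @examples
#' vs <- simulate_variome(n_genes = 10, seed = 1)
#' head(vs$truth)
#' @export
simulate_variome <- function(n_genes = 100, flank_length = 3000,
                             body_length_range = c(1000, 5000),
                             density_upstream = 0.01, density_body = 0.005,
                             density_downstream = 0.01, n_samples = 20,
                             chrom = "chrSim", seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes", 1)
  n_samples <- check_count(n_samples, "n_samples", 2)
  dens <- c(upstream = density_upstream, body = density_body,
            downstream = density_downstream)
  if (any(dens < 0)) abort("Variant densities must be non-negative.")
  if (any(dens > 1)) abort("Variant densities are per bp and cannot exceed 1.")
  local_seed(seed)

  gap <- 2 * flank_length + 1000        # keeps neighbouring flanks disjoint
  body_len <- as.integer(round(runif(n_genes, body_length_range[1],
                                     body_length_range[2])))
  start <- flank_length + 1000 + c(0, cumsum(head(body_len, -1) + gap))
  genes <- tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    chrom = chrom,
    start = start,
    end = start + body_len - 1L,
    strand = rep_len(c("+", "-"), n_genes)
  )
  chrom_length <- max(genes$end) + flank_length + 1000

  regions <- gene_regions(genes, flank = flank_length,
                          chrom_lengths = setNames(chrom_length, chrom))
  regions$density <- dens[regions$region]

  bases <- c("A", "C", "G", "T")
  # expected per-site pi for ac ~ Uniform{1..n-1}: (n+1) / (3 (n-1))
  e_site_pi <- (n_samples + 1) / (3 * (n_samples - 1))

  site_list <- purrr::pmap(
    regions[c("start", "end", "density")],
    function(start, end, density) {
      len <- end - start + 1
      n_var <- rbinom(1, len, density)
      if (n_var == 0) return(NULL)
      pos <- sort(sample(seq(start, end), n_var))
      tibble::tibble(pos = pos)
    }
  )
  regions$n_sites <- vapply(site_list, function(x) if (is.null(x)) 0L else nrow(x),
                            integer(1))
  variants <- dplyr::bind_rows(site_list)

  if (nrow(variants) > 0) {
    # flanks of neighbouring genes are disjoint by construction, but guard anyway
    variants <- dplyr::distinct(variants, .data$pos)
    n_var <- nrow(variants)
    ref <- sample(bases, n_var, replace = TRUE)
    alt <- unname(vapply(ref, function(b) sample(setdiff(bases, b), 1),
                         character(1)))
    ac <- sample(n_samples - 1L, n_var, replace = TRUE)
    geno <- matrix(0L, n_var, n_samples,
                   dimnames = list(NULL, sprintf("S%03d", seq_len(n_samples))))
    for (i in seq_len(n_var)) geno[i, sample(n_samples, ac[i])] <- 1L
    variants <- tibble::tibble(
      chrom = chrom, pos = variants$pos, ref = ref, alt = alt,
      ac = ac, an = n_samples
    )
  } else {
    variants <- tibble::tibble(
      chrom = character(), pos = numeric(), ref = character(),
      alt = character(), ac = integer(), an = integer()
    )
    geno <- matrix(0L, 0, n_samples,
                   dimnames = list(NULL, sprintf("S%03d", seq_len(n_samples))))
  }

  truth <- dplyr::transmute(
    regions,
    gene_id = .data$gene_id, region = .data$region,
    length = .data$end - .data$start + 1,
    expected_pi = .data$density * e_site_pi
  )

  structure(
    list(
      variants = variants, genotypes = geno, genes = genes, truth = truth,
      n_samples = n_samples, chrom_length = chrom_length,
      flank_length = flank_length, densities = dens, seed = seed
    ),
    class = "variome_sim"
  )
}

#' @export
print.variome_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic variome: %d genes, %d variant sites, %d haplotypes on %s (%g bp)\n",
    nrow(x$genes), nrow(x$variants), x$n_samples, x$genes$chrom[1],
    x$chrom_length
  ))
  invisible(x)
}
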