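#' End-to-end synthetic demonstration run
#'
#' Chains every stage of the package on synthetic data generated under one
#' seed: simulate an F2 cross segregating a recessive locus, test the
#' phenotype ratio against 3:1, run the bulked-segregant delta SNP-index
#' scan with its Monte-Carlo envelope, narrow the locus with a panel of
#' homozygous recombinant lines and count genes in the interval, profile a
#' promoter family's conservation and the overlap of a 416-bp deletion with
#' its conserved blocks, and rank a focal gene's upstream diversity within a
#' synthetic variome. Two runs with the same seed produce byte-identical
#' outputs.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there (TSV/BED/FASTA/VCF/GFF3 plus a `manifest.tsv` of file
#'   checksums).
#' @param n_f2 F2 population size (default 200).
#' @param chrom_length Chromosome length in bp (default 5e7).
#' @param snp_spacing Marker spacing in bp (default 1e4).
#' @param causal_position Causal locus position (default 2.5e7).
#' @param bulk_size Individuals per bulk (default 30).
#' @param mean_depth Mean sequencing depth per bulk (default 30).
#' @param n_sims Envelope simulations (default 10000).
#' @param n_lines Homozygous recombinant lines for fine-mapping (default 60).
#' @param n_genes_variome Genes in the synthetic variome (default 60).
#' @return A `bulkmapr_demo` list with elements `segregation`, `bsa`,
#'   `fine_mapping`, `conservation`, `diversity`, `quant` and `params`.
#' @examples
#' \donttest{
#' demo <- run_demo(seed = 1, n_sims = 500, chrom_length = 1e7,
#'                  causal_position = 5e6)
#' demo$bsa$regions
#' }
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_f2 = 200,
                     chrom_length = 5e7, snp_spacing = 1e4,
                     causal_position = 2.5e7, bulk_size = 30,
                     mean_depth = 30, n_sims = 10000, n_lines = 200,
                     n_genes_variome = 60) {
  local_seed(seed)

  ## 1. cross + segregation ratio
  markers <- seq(snp_spacing, chrom_length, by = snp_spacing)
  pop <- simulate_f2(n_f2, markers, causal_position, chrom_length,
                     chrom = "chr6")
  counts <- c(sum(pop$phenotype == "wildtype"), sum(pop$phenotype == "mutant"))
  seg <- chisq_gof(counts, c(3, 1), correction = TRUE,
                   labels = c("wildtype", "mutant"))
  seg_out <- list(observed = counts, test = seg,
                  fit = classify_fit(seg, 0.05))

  ## 2. bulked-segregant scan
  bulks <- make_bulks(pop, bulk_size, bulk_size)
  bulk_counts <- simulate_bulk_reads(pop, bulks, mean_depth = mean_depth)
  scan <- bsa_scan(bulk_counts, bulk_size, bulk_size, n_sims = n_sims,
                   chrom_lengths = c(chr6 = chrom_length))

  ## 3. fine-mapping inside the scan peak
  fm_markers <- tibble::tibble(
    marker = sprintf("SNP-%02d", 1:21),
    chrom = "chr6",
    pos = causal_position + seq(-500000, 500000, by = 50000)
  )
  lines <- simulate_recombinant_lines(n_lines, fm_markers, causal_position)
  interval <- infer_interval(lines$panel, fm_markers, homozygous_lines = TRUE)
  lengths <- dplyr::bind_rows(
    interval_length(interval, "flank"),
    interval_length(interval, "inclusive")
  )
  genes_fm <- tibble::tibble(
    gene_id = sprintf("demo_g%03d", 1:140),
    chrom = "chr6",
    start = causal_position - 500000 + (0:139) * 7000,
    end = causal_position - 500000 + (0:139) * 7000 + 1999,
    strand = rep_len(c("+", "-"), 140)
  )
  in_interval <- genes_in_interval(genes_fm, interval)
  fm_out <- list(markers = fm_markers, panel = lines$panel,
                 interval = interval, lengths = lengths,
                 genes = genes_fm, genes_in_interval = in_interval)

  ## 4. promoter conservation + deletion overlap
  ## The alignment spans five intact lineages; the 416-bp deletion of the
  ## mutant line enters as externally supplied reference coordinates, as it
  ## would from a structural-variant call against the reference genome.
  fam <- simulate_promoter_family(
    ancestral_length = 5000, n_lineages = 5,
    conserved_blocks = list(c(1001, 1600), c(3001, 3700))
  )
  deletion_iv <- c(3100, 3515)                 # 416 bp inside block 2
  profile <- window_diversity(fam$alignment, reference = fam$alignment$label[1])
  conserved <- call_conserved(profile, threshold = 0.3)
  overlap <- sv_overlap(fam$alignment, deletion_iv,
                        reference = fam$alignment$label[1])
  cons_out <- list(family = fam, profile = profile, conserved = conserved,
                   sv_overlap = overlap,
                   fraction_covered = attr(overlap, "fraction_covered"))

  ## 5. variome diversity + focal-gene rank (focal upstream held invariant)
  vs <- simulate_variome(n_genes = n_genes_variome)
  focal <- vs$genes$gene_id[1]
  up <- gene_regions(vs$genes[1, ], flank = vs$flank_length)
  up <- up[up$region == "upstream", ]
  keep <- !(vs$variants$pos >= up$start & vs$variants$pos <= up$end)
  variants <- vs$variants[keep, , drop = FALSE]
  regions <- gene_regions(vs$genes, flank = vs$flank_length,
                          chrom_lengths = setNames(vs$chrom_length, "chrSim"))
  pis <- pi_summary(variants, regions)
  rank <- rank_gene(pis, focal, "upstream")
  pi_out <- list(variome = vs, summary = pis, focal = focal, rank = rank)

  ## 6. assay utilities on small synthetic tables
  ct <- tibble::tibble(
    sample = c("WT", "aff"),
    ct_target = c(24.0, 26.5),
    ct_ref1 = c(20, 20.1), ct_ref2 = c(22, 21.9), ct_ref3 = c(24, 24)
  )
  quant <- list(
    ddct = ddct_fold_change(ct, calibrator = "WT"),
    luc = luc_ren_ratio(
      tibble::tibble(
        construct = rep(c("promoter_wt", "promoter_del"), each = 3),
        firefly = c(5.8, 6.3, 6.1, 2.0, 2.2, 1.9),
        renilla = rep(2.0, 6)
      ),
      group = "construct"
    )
  )

  result <- structure(
    list(
      segregation = seg_out, bsa = scan, fine_mapping = fm_out,
      conservation = cons_out, diversity = pi_out, quant = quant,
      params = list(
        seed = seed, n_f2 = n_f2, chrom_length = chrom_length,
        snp_spacing = snp_spacing, causal_position = causal_position,
        bulk_size = bulk_size, mean_depth = mean_depth, n_sims = n_sims
      )
    ),
    class = "bulkmapr_demo"
  )
  if (!is.null(out_dir)) write_demo_outputs(result, bulk_counts, out_dir)
  result
}

write_demo_outputs <- function(result, bulk_counts, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  write_bulk_counts(bulk_counts, p("bulk_counts.tsv"))
  write_profile_tsv(result$bsa$profile, p("bsa_profile.tsv"))
  write_profile_tsv(result$bsa$envelope, p("bsa_envelope.tsv"))
  if (nrow(result$bsa$regions) > 0) {
    write_bed(result$bsa$regions, p("bsa_regions.bed"))
  }
  iv <- result$fine_mapping$interval
  write_tsv_commented(tibble::as_tibble(iv), p("interval.tsv"),
                      "coordinates: 1-based positions of flanking markers")
  write_tsv_commented(result$fine_mapping$lengths, p("interval_lengths.tsv"))
  write_gff3_genes(result$fine_mapping$genes, p("genes.gff3"))
  write_alignment_fasta(result$conservation$family$alignment,
                        p("promoter_alignment.fasta"))
  write_profile_tsv(result$conservation$profile, p("conservation_profile.tsv"))
  if (nrow(result$conservation$conserved) > 0) {
    bed <- dplyr::mutate(result$conservation$conserved, chrom = "reference")
    write_bed(bed, p("conserved_regions.bed"))
  }
  vs <- result$diversity$variome
  write_vcf_panel(vs$variants, vs$genotypes, p("variome.vcf"))
  write_gff3_genes(vs$genes, p("variome_genes.gff3"))
  write_tsv_commented(tibble::as_tibble(result$diversity$summary),
                      p("pi_summary.tsv"), "coordinates: 1-based inclusive")
  write_tsv_commented(result$diversity$rank, p("pi_rank.tsv"))

  files <- sort(list.files(out_dir))
  files <- files[files != "manifest.tsv"]
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    seed = result$params$seed,
    package_version = as.character(utils::packageVersion("bulkmapr"))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.bulkmapr_demo <- function(x, ...) {
  cat("bulkmapr synthetic demonstration run (seed", x$params$seed, ")\n")
  cat(sprintf("  segregation: %d:%d vs 3:1, X2 = %.3f (%s)\n",
              x$segregation$observed[1], x$segregation$observed[2],
              x$segregation$test$chisq, x$segregation$fit))
  if (nrow(x$bsa$regions) > 0) {
    r <- x$bsa$regions[which.max(x$bsa$regions$peak_delta), ]
    cat(sprintf("  BSA peak: %s:%0.0f-%0.0f, peak delta = %.2f\n",
                r$chrom, r$start, r$end, r$peak_delta))
  } else cat("  BSA: no significant region\n")
  iv <- x$fine_mapping$interval
  cat(sprintf("  fine-mapped interval: %s:%0.0f-%0.0f (%d genes)\n",
              iv$chrom, iv$left, iv$right, nrow(x$fine_mapping$genes_in_interval)))
  cat(sprintf("  promoter: %d conserved region(s); deletion overlap fraction %.2f\n",
              nrow(x$conservation$conserved), x$conservation$fraction_covered))
  cat(sprintf("  focal upstream pi = %.4g, greater in %.1f%% of other genes\n",
              x$diversity$rank$pi, x$diversity$rank$percent_greater))
  invisible(x)
}
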