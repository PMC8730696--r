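# All tabular writers emit a "# coordinates:" comment line so files are
# self-describing; readers skip "#" comments. VCF/GFF3 are 1-based inclusive,
# BED is 0-based half-open.

write_tsv_commented <- function(x, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(path)
}

#' Read and write bulk allele-count tables
#'
#' Long TSV with columns `chrom`, `pos`, `bulk`, `depth`, `mut_count`
#' (1-based positions), the interchange format between the cross simulator
#' and the bulked-segregant scan.
#'
#' @param counts Tibble as produced by [simulate_bulk_reads()].
#' @param path File path.
#' @return `read_bulk_counts()` returns the tibble; `write_bulk_counts()`
#'   the path, invisibly.
#' @export
write_bulk_counts <- function(counts, path) {
  req <- c("chrom", "pos", "bulk", "depth", "mut_count")
  if (!all(req %in% names(counts))) {
    abort(paste("`counts` must have columns:", paste(req, collapse = ", ")))
  }
  write_tsv_commented(counts[req], path, "coordinates: 1-based positions")
}

#' @rdname write_bulk_counts
#' @export
read_bulk_counts <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = "c", pos = "d", bulk = "c",
                    depth = "i", mut_count = "i"
                  ))
}

#' Read and write BED intervals
#'
#' Converts between the package's 1-based inclusive intervals and BED's
#' 0-based half-open convention on disk.
#'
#' @param x Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optionally `name`.
#' @param path File path.
#' @return `read_bed()` returns a 1-based inclusive tibble.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' write_bed(tibble::tibble(chrom = "c1", start = 101, end = 200), f)
#' readLines(f)   # "c1\t100\t200"
#' @export
write_bed <- function(x, path) {
  out <- tibble::tibble(
    chrom = x$chrom,
    start = format(x$start - 1, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE)
  )
  if ("name" %in% names(x)) out$name <- x$name
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  out <- tibble::tibble(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]) + 1,
    end = as.numeric(raw[[3]])
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}

#' Write a minimal haploid VCF v4.2
#'
#' Serializes a variant panel with per-sample GT fields (haploid 0/1 calls,
#' `.` for missing). The complementary [read_vcf_panel()] parses any VCF via
#' the vcfR package and reduces biallelic SNP records to allele counts;
#' indel, multiallelic and non-SNP records are skipped with a counted
#' warning.
#'
#' @param variants Tibble `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes 0/1/NA integer matrix, sites x samples, column names =
#'   sample names.
#' @param path File path.
#' @export
write_vcf_panel <- function(variants, genotypes, path) {
  if (nrow(variants) != nrow(genotypes)) {
    abort("`variants` and `genotypes` must have the same number of sites.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bulkmapr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  ), con)
  if (nrow(variants) > 0) {
    gt <- matrix(as.character(genotypes), nrow = nrow(genotypes))
    gt[is.na(gt)] <- "."
    body <- paste(
      variants$chrom, format(variants$pos, scientific = FALSE, trim = TRUE),
      ".", variants$ref, variants$alt, ".", "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' @rdname write_vcf_panel
#' @return `read_vcf_panel()` returns a tibble `chrom`, `pos`, `ref`,
#'   `alt`, `ac`, `an` with the genotype matrix as attribute `genotypes`
#'   and a `skipped` attribute counting non-biallelic-SNP records.
#' @export
read_vcf_panel <- function(path) {
  need_pkg("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  skipped <- sum(!snp)
  if (skipped > 0) {
    warn(sprintf("%d non-biallelic-SNP record(s) skipped.", skipped))
  }
  fix <- fix[snp, , drop = FALSE]
  gt_raw <- gt_raw[snp, , drop = FALSE]
  # haploid "0"/"1" or diploid "0/1"-style calls both reduce to allele counts
  count_alt <- function(g) {
    alleles <- strsplit(g, "[/|]")
    vapply(alleles, function(a) {
      a <- a[a %in% c("0", "1")]
      c(sum(a == "1"), length(a))
    }, numeric(2))
  }
  res <- apply(gt_raw, 1, function(row) rowSums(count_alt(row)))
  geno <- suppressWarnings(matrix(as.integer(gt_raw == "1"),
                                  nrow = nrow(gt_raw),
                                  dimnames = dimnames(gt_raw)))
  out <- tibble::tibble(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    ac = as.integer(res[1, ]), an = as.integer(res[2, ])
  )
  attr(out, "genotypes") <- geno
  attr(out, "skipped") <- skipped
  out
}

#' Read and write gene models as GFF3
#'
#' `write_gff3_genes()` serializes a gene table to GFF3 (1-based inclusive,
#' `gene` features with `ID` attributes); `read_gff3_genes()` parses a GFF3
#' via rtracklayer and returns the gene features as a tibble.
#'
#' @param genes Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path File path.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(paste(
      genes$chrom, "bulkmapr", "gene",
      format(genes$start, scientific = FALSE, trim = TRUE),
      format(genes$end, scientific = FALSE, trim = TRUE),
      ".", genes$strand, ".", paste0("ID=", genes$gene_id),
      sep = "\t"
    ), con)
  }
  invisible(path)
}

#' @rdname write_gff3_genes
#' @return `read_gff3_genes()` returns a tibble `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (strand `"."` is kept as `NA` and rejected
#'   later by [gene_regions()]).
#' @export
read_gff3_genes <- function(path) {
  need_pkg("rtracklayer")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  strand <- as.character(BiocGenerics::strand(gr))
  tibble::tibble(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = ifelse(strand %in% c("+", "-"), strand, NA_character_)
  )
}

#' Read and write gapped alignment FASTA
#'
#' Thin wrappers over Biostrings preserving gap characters, moving
#' alignments between files and the package's `label`/`sequence` tibbles.
#'
#' @param alignment Tibble with `label`, `sequence`.
#' @param path File path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  need_pkg("Biostrings")
  x <- Biostrings::BStringSet(setNames(alignment$sequence, alignment$label))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  need_pkg("Biostrings")
  x <- Biostrings::readBStringSet(path)
  tibble::tibble(label = names(x), sequence = toupper(as.character(x)))
}

#' Write a window profile or envelope TSV
#'
#' @param x A `bsa_profile`, `bsa_envelope` or `conservation_profile`.
#' @param path File path.
#' @export
write_profile_tsv <- function(x, path) {
  write_tsv_commented(tibble::as_tibble(x), path,
                      "coordinates: 1-based inclusive window bounds")
}
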