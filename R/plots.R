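#' Plot a delta SNP-index window profile
#'
#' Genome-scan view: windowed mean delta SNP-index along the chromosome,
#' with the null envelope threshold and any called candidate regions
#' shaded.
#'
#' @param object A `bsa_profile` from [window_profile()].
#' @param envelope Optional `bsa_envelope`; draws the per-window threshold
#'   at `level`.
#' @param regions Optional `bsa_regions` to shade.
#' @param level Envelope percentile to draw (default 99).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsa_profile
#' @export
autoplot.bsa_profile <- function(object, envelope = NULL, regions = NULL,
                                 level = 99, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df[!df$missing, ],
                       ggplot2::aes(x = .data$mid / 1e6, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(Delta * " SNP-index")) +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    qcol <- paste0("q", level)
    idx <- match(df$n_snps, envelope$n_snps)
    idx[is.na(idx)] <- vapply(df$n_snps[is.na(idx)], function(m) {
      which.min(abs(envelope$n_snps - m))
    }, integer(1))
    df$threshold <- envelope[[qcol]][idx]
    p <- p + ggplot2::geom_line(
      data = df[!df$missing, ],
      ggplot2::aes(y = .data$threshold),
      colour = "firebrick", linetype = 2
    )
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(regions),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot a promoter conservation profile
#'
#' Windowed diversity along the reference promoter with the conservation
#' threshold, called conserved regions, and (optionally) a structural
#' variant interval marked.
#'
#' @param object A `conservation_profile` from [window_diversity()].
#' @param threshold Diversity threshold line (default 0.3).
#' @param sv Optional `c(start, end)` reference interval to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, threshold = 0.3, sv = NULL,
                                          ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$start + df$end) / 2
  regions <- call_conserved(object, threshold = threshold)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$diversity)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "Reference position (bp)", y = "Diversity") +
    ggplot2::theme_minimal()
  if (nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "seagreen",
      inherit.aes = FALSE
    )
  }
  if (!is.null(sv)) {
    p <- p + ggplot2::annotate("rect", xmin = sv[1], xmax = sv[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.25,
                               fill = "orange")
  }
  p
}

#' Plot per-region nucleotide diversity distributions
#'
#' Violin view of the genome-wide pi distribution per region class
#' (upstream flank, gene body, downstream flank) with optional focal genes
#' highlighted — the standard presentation for asking whether a focal
#' promoter is unusually conserved.
#'
#' @param summary A [pi_summary()] tibble.
#' @param focal Optional character vector of focal gene ids to overlay.
#' @return A ggplot object.
#' @export
plot_pi_distribution <- function(summary, focal = NULL) {
  df <- tibble::as_tibble(summary)
  df$region <- factor(df$region, c("upstream", "body", "downstream"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$pi)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::labs(x = NULL, y = expression(pi)) +
    ggplot2::theme_minimal()
  if (!is.null(focal)) {
    p <- p + ggplot2::geom_point(
      data = df[df$gene_id %in% focal, ],
      colour = "firebrick", size = 3, shape = 18
    )
  }
  p
}
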