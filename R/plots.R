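#' Genome-wide log-ratio and MAF profile plot
#'
#' Two stacked panels in the style of standard copy-number review plots:
#' per-bin coverage log-ratios (top) and het-SNP minor allele fractions
#' (bottom) along the genome, with fitted segment expectations overlaid
#' when a model is supplied.
#'
#' @param profile Log-ratio profile ([compute_log_ratio()]).
#' @param maf Het-SNP profile ([select_het_snps()]).
#' @param model Optional `sgz_cn_model` whose expectations are drawn as
#'   segment-wise lines.
#' @return A ggplot object.
#' @export
plot_genome_profile <- function(profile, maf = NULL, model = NULL) {
  chroms <- unique(profile$chrom)
  offset_of <- function(chrom) {
    sizes <- vapply(chroms, function(ch) {
      max(profile$end[profile$chrom == ch])
    }, 0)
    cum <- cumsum(c(0, utils::head(sizes, -1)))
    stats::setNames(cum, chroms)[chrom]
  }
  d_lr <- profile |>
    dplyr::mutate(x = .data$start + offset_of(.data$chrom),
                  panel = "log-ratio", y = .data$log_ratio)
  d <- d_lr
  if (!is.null(maf) && nrow(maf)) {
    d_maf <- maf |>
      dplyr::filter(.data$chrom %in% chroms) |>
      dplyr::mutate(x = .data$pos + offset_of(.data$chrom),
                    panel = "minor allele fraction", y = .data$maf)
    d <- dplyr::bind_rows(d_lr, d_maf[, c("chrom", "x", "panel", "y")])
  }
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "genome position", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    seg <- model$segments |>
      dplyr::mutate(x0 = .data$start + offset_of(.data$chrom),
                    x1 = .data$end + offset_of(.data$chrom))
    seg_lr <- seg |> dplyr::mutate(panel = "log-ratio", y = .data$expected_lr)
    seg_maf <- seg |>
      dplyr::filter(!is.na(.data$expected_maf)) |>
      dplyr::mutate(panel = "minor allele fraction", y = .data$expected_maf)
    segs <- dplyr::bind_rows(seg_lr, seg_maf)
    g <- g + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y,
                   yend = .data$y),
      inherit.aes = FALSE, colour = "black", linewidth = 0.7
    )
  }
  g
}

#' @rdname plot_genome_profile
#' @param object `sgz_cn_model`.
#' @param ... Unused.
#' @method autoplot sgz_cn_model
#' @export
autoplot.sgz_cn_model <- function(object, ...) {
  seg <- object$segments
  d <- seg |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$segment)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_lr), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_lr),
                        colour = "firebrick", shape = 3, size = 2) +
    ggplot2::labs(
      x = "segment", y = "median log-ratio",
      title = sprintf("purity %.2f, ploidy %.2f (%s fit)",
                      object$purity, object$ploidy, object$source)
    ) +
    ggplot2::theme_minimal()
}

#' Allele-frequency scatter of classified variants
#'
#' Observed allele fraction per variant, coloured by SGZ status, with the
#' germline and somatic expectations of each variant's segment marked.
#'
#' @param object `sgz_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sgz_calls
#' @export
autoplot.sgz_calls <- function(object, ...) {
  d <- dplyr::mutate(object, idx = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$af,
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$af_germline), shape = 95,
                        size = 5, colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$af_somatic), shape = 95,
                        size = 5, colour = "firebrick", na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "variant", y = "allele fraction",
                  colour = "SGZ status") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
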