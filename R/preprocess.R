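#' Median-normalized coverage log-ratio profile
#'
#' Divides tumor read depth by the process-matched normal depth per bin,
#' takes log2, and centers the profile on its median so that the modal copy
#' state sits near zero. Bins where either depth is zero carry no usable
#' ratio and are dropped (their count is kept in the `n_dropped` attribute).
#'
#' @param bins Coverage tibble with columns `chrom`, `start`, `end`, `gc`,
#'   `tumor_depth`, `normal_depth`.
#' @return A tibble (`chrom`, `start`, `end`, `gc`, `log_ratio`) with
#'   attributes `n_dropped` and `median_normalized = TRUE`.
#' @export
compute_log_ratio <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "tumor_depth", "normal_depth")
                %in% names(bins)))
  keep <- bins$normal_depth > 0 & bins$tumor_depth > 0
  out <- bins[keep, ]
  if (nrow(out) == 0) stop("no usable coverage: all bins have zero depth")
  if (!"gc" %in% names(out)) out$gc <- NA_real_
  out <- out |>
    dplyr::mutate(log_ratio = log2(.data$tumor_depth / .data$normal_depth)) |>
    dplyr::select("chrom", "start", "end", "gc", "log_ratio")
  out$log_ratio <- out$log_ratio - stats::median(out$log_ratio)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "median_normalized") <- TRUE
  out
}

#' GC-content bias correction by Lowess regression
#'
#' Fits a Lowess smooth of log-ratio against GC fraction, subtracts the
#' fitted trend, and re-centers on the median. With fewer than `min_bins`
#' bins there is too little support for a smooth and the profile is
#' returned unchanged with a warning.
#'
#' @param profile Output of [compute_log_ratio()].
#' @param span Lowess smoother span (fraction of points).
#' @param iter Robustness iterations.
#' @param min_bins Minimum bins required to attempt the correction.
#' @return Corrected log-ratio profile, same shape as the input.
#' @export
gc_correct <- function(profile, span = 0.3, iter = 1L, min_bins = 30L) {
  stopifnot(all(c("gc", "log_ratio") %in% names(profile)))
  if (nrow(profile) < min_bins) {
    warning("fewer than ", min_bins, " bins; GC correction skipped")
    return(profile)
  }
  stopifnot(all(profile$gc >= 0 & profile$gc <= 1))
  if (stats::sd(profile$gc) == 0) {
    # constant GC: the trend is a constant, removed by re-centering anyway
    profile$log_ratio <- profile$log_ratio - stats::median(profile$log_ratio)
    return(profile)
  }
  fit <- stats::lowess(profile$gc, profile$log_ratio, f = span, iter = iter)
  trend <- stats::approx(fit$x, fit$y, xout = profile$gc, rule = 2)$y
  profile$log_ratio <- profile$log_ratio - trend
  profile$log_ratio <- profile$log_ratio - stats::median(profile$log_ratio)
  profile
}

#' Select heterozygous SNPs and fold to minor allele fraction
#'
#' Without a matched normal, heterozygosity is inferred from the tumor
#' allele fraction itself: SNPs with alt fraction inside the window
#' `[het_lo, het_hi]` at adequate depth are taken as germline-heterozygous.
#' The window must stay wide enough to retain het SNPs displaced from 0.5
#' by LOH at moderate purity; it is the main sensitivity knob of the
#' preprocessing. Retained SNPs are folded to minor allele fraction
#' `min(f, 1 - f)`.
#'
#' @param snps Tibble with `chrom`, `pos`, `depth`, `alt_depth`.
#' @param min_depth Minimum read depth (default 20).
#' @param het_lo,het_hi Alt-fraction window for calling a SNP heterozygous.
#' @return Tibble (`chrom`, `pos`, `depth`, `af`, `maf`) of het SNPs; `af`
#'   is the unfolded alt fraction, `maf` the folded minor fraction.
#' @export
select_het_snps <- function(snps, min_depth = 20, het_lo = 0.10,
                            het_hi = 0.90) {
  stopifnot(all(c("chrom", "pos", "depth", "alt_depth") %in% names(snps)))
  snps |>
    dplyr::filter(.data$depth >= min_depth) |>
    dplyr::mutate(af = .data$alt_depth / .data$depth) |>
    dplyr::filter(.data$af >= het_lo, .data$af <= het_hi) |>
    dplyr::mutate(maf = pmin(.data$af, 1 - .data$af)) |>
    dplyr::select("chrom", "pos", "depth", "af", "maf")
}
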