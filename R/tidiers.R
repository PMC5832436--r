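#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted copy-number model
#'
#' One row per segment: coordinates, fitted copy number `C` and minor
#' allele count `M`, observed and expected log-ratio and MAF.
#'
#' @param x `sgz_cn_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sgz_cn_model
#' @export
tidy.sgz_cn_model <- function(x, ...) {
  tibble::as_tibble(x$segments)
}

#' Model-level summary of a fitted copy-number model
#'
#' @param x `sgz_cn_model`.
#' @param ... Unused.
#' @return One-row tibble: purity, ploidy, MSEs, source, number of
#'   segments, flags (comma-separated).
#' @method glance sgz_cn_model
#' @export
glance.sgz_cn_model <- function(x, ...) {
  tibble::tibble(
    purity = x$purity, ploidy = x$ploidy, mse_lr = x$mse_lr,
    mse_maf = x$mse_maf, source = x$source,
    n_segments = nrow(x$segments),
    rhat = x$rhat %||% NA_real_,
    flags = paste(x$flags, collapse = ",")
  )
}

#' Summary of a call set
#'
#' @param x `sgz_calls` tibble.
#' @param ... Unused.
#' @return One-row tibble: total variants, per-status counts, call rate.
#' @method glance sgz_calls
#' @export
glance.sgz_calls <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_somatic = sum(x$status == "somatic"),
    n_germline = sum(x$status == "germline"),
    n_subclonal = sum(x$status == "subclonal_somatic"),
    n_ambiguous = sum(x$status == "ambiguous"),
    call_rate = if (nrow(x)) mean(x$status != "ambiguous") else NA_real_
  )
}
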