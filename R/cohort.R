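#' Tally per-sample calls of recurrent variants
#'
#' Counts, for every distinct variant key across samples, the number of
#' germline calls (`n_G`), somatic calls (`n_S`, subclonal somatic
#' included), and ambiguous calls (tallied separately; they carry no
#' likelihood weight in the posterior).
#'
#' @param calls Tibble of per-sample calls (rows from [classify_variants()],
#'   any number of samples bound together) with columns `chrom`, `pos`,
#'   `ref`, `alt`, `status`.
#' @return Tibble: variant key, `n_G`, `n_S`, `n_ambiguous`.
#' @export
tally_calls <- function(calls) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "status") %in% names(calls)))
  calls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_G = sum(.data$status == "germline"),
      n_S = sum(.data$status %in% c("somatic", "subclonal_somatic")),
      n_ambiguous = sum(.data$status == "ambiguous"),
      .groups = "drop"
    )
}

#' Posterior probability that a recurrent variant is somatic
#'
#' Aggregates `n_G` germline and `n_S` somatic per-sample calls under
#' binomial error models with a flat prior: given a truly germline variant,
#' each somatic call is an error of rate `e_G`; given a truly somatic one,
#' each germline call is an error of rate `e_S`. Then
#' \deqn{P(S \mid n_G, n_S) = \frac{P(n_G,n_S \mid S)}{P(n_G,n_S \mid G) + P(n_G,n_S \mid S)}}
#' with \eqn{P(n_G,n_S|G) = \binom{n_G+n_S}{n_G} e_G^{n_S} (1-e_G)^{n_G}}
#' and \eqn{P(n_G,n_S|S) = \binom{n_G+n_S}{n_S} e_S^{n_G} (1-e_S)^{n_S}}.
#' Evaluated in log space, so posteriors remain finite and correctly
#' ordered for counts in the thousands (magnitudes down to 1e-300 and
#' below are representable through the log odds).
#'
#' The default error rates are deliberately conservative (higher than the
#' per-sample error observed in validation).
#'
#' @param n_G,n_S Non-negative call counts (vectorised).
#' @param e_G Single-sample germline error rate (default 0.05).
#' @param e_S Single-sample somatic error rate (default 0.10).
#' @return Tibble with `P_somatic`, `P_germline`, and `log10_P_somatic`
#'   (exact even when `P_somatic` underflows a double).
#' @export
cohort_posterior <- function(n_G, n_S, e_G = 0.05, e_S = 0.10) {
  stopifnot(all(n_G >= 0), all(n_S >= 0),
            e_G > 0, e_G < 1, e_S > 0, e_S < 1)
  log_pg <- lchoose(n_G + n_S, n_G) + n_S * log(e_G) + n_G * log1p(-e_G)
  log_ps <- lchoose(n_G + n_S, n_S) + n_G * log(e_S) + n_S * log1p(-e_S)
  # log odds of somatic vs germline; flat prior cancels
  lo <- log_ps - log_pg
  p_som <- stats::plogis(lo)
  tibble::tibble(
    P_somatic = p_som,
    P_germline = stats::plogis(-lo),
    log10_P_somatic = (stats::plogis(lo, log.p = TRUE)) / log(10)
  )
}

#' Aggregate a cohort of per-sample calls into posteriors
#'
#' Convenience wrapper: [tally_calls()] then [cohort_posterior()] per
#' variant key.
#'
#' @inheritParams tally_calls
#' @inheritParams cohort_posterior
#' @return Tibble: variant key, counts, `P_somatic`, `P_germline`,
#'   `log10_P_somatic`.
#' @export
aggregate_cohort <- function(calls, e_G = 0.05, e_S = 0.10) {
  t <- tally_calls(calls)
  dplyr::bind_cols(t, cohort_posterior(t$n_G, t$n_S, e_G, e_S))
}
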