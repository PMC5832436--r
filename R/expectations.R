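#' Expected coverage log-ratio for a copy-number state
#'
#' Mean of the coverage log-ratio of a genomic segment with integer tumor
#' copy number `C`, in a specimen of tumor purity `p` and tumor ploidy `psi`.
#' The tumor contributes `p * C` copies and the admixed diploid normal
#' `2 * (1 - p)`; the denominator is the genome-average copy number of the
#' admixed specimen, so a segment at the ploidy has log-ratio 0:
#'
#' \deqn{E[r] = \log_2\frac{pC + 2(1-p)}{p\Psi + 2(1-p)}}
#'
#' @param p Tumor purity, fraction in \[0, 1\].
#' @param C Tumor copy number of the segment, non-negative integer (vectorised).
#' @param psi Tumor ploidy (length-weighted mean copy number), > 0.
#' @return Expected log2 ratio; `-Inf` for the degenerate pure-tumor
#'   homozygous deletion (`p = 1`, `C = 0`).
#' @examples
#' expected_log_ratio(1, 4, 2)    # 1: a four-copy gain in a pure diploid tumor
#' expected_log_ratio(0, 7, 2)    # 0: no tumor signal at purity 0
#' expected_log_ratio(0.5, 3, 2)  # log2(2.5/2)
#' @export
expected_log_ratio <- function(p, C, psi) {
  stopifnot(all(p >= 0 & p <= 1), all(C >= 0), all(psi > 0))
  num <- p * C + 2 * (1 - p)
  den <- p * psi + 2 * (1 - p)
  log2(num / den)
}

#' Expected minor allele frequency of heterozygous SNPs in a segment
#'
#' Mean minor allele frequency at germline-heterozygous SNPs in a segment
#' with tumor copy number `C` of which `M` copies carry the minor allele
#' (`0 <= M <= C/2`), at purity `p`. Each normal cell contributes one copy of
#' either allele:
#'
#' \deqn{E[f] = \frac{pM + 1 - p}{pC + 2(1-p)}}
#'
#' @inheritParams expected_log_ratio
#' @param M Minor-allele copy count, `0 <= M <= floor(C/2)` (vectorised).
#' @return Expected minor allele fraction in \[0, 0.5\]; `NaN` for the
#'   undefined `p = 1, C = 0` state.
#' @examples
#' expected_maf(1, 2, 1)    # 0.5: pure tumor, balanced
#' expected_maf(0, 5, 1)    # 0.5: the normal is heterozygous
#' expected_maf(0.5, 2, 0)  # 0.25: LOH at half purity
#' @export
expected_maf <- function(p, C, M) {
  stopifnot(all(p >= 0 & p <= 1), all(C >= 0), all(M >= 0), all(2 * M <= C))
  (p * M + 1 - p) / (p * C + 2 * (1 - p))
}

#' Tumor ploidy from segment lengths and copy numbers
#'
#' The length-weighted mean copy number, \eqn{\Psi = \sum_i l_i C_i / \sum_i l_i}.
#'
#' @param lengths Positive segment lengths (bin counts or base pairs).
#' @param copy_numbers Integer copy numbers, same length as `lengths`.
#' @return Ploidy, a positive scalar.
#' @examples
#' compute_ploidy(c(3, 1), c(2, 6))  # 3
#' @export
compute_ploidy <- function(lengths, copy_numbers) {
  if (length(lengths) == 0L) stop("cannot compute ploidy of an empty genome")
  stopifnot(length(lengths) == length(copy_numbers), all(lengths > 0))
  sum(lengths * copy_numbers) / sum(lengths)
}

#' Expected allele frequency of a germline variant
#'
#' A germline variant is carried by one of the two alleles of every normal
#' cell and by `V` of the `C` tumor copies at its segment:
#'
#' \deqn{AF_{germline} = \frac{pV + 1 - p}{pC + 2(1-p)}}
#'
#' A heterozygous germline variant in a copy-neutral balanced segment
#' (`C = 2`, `V = 1`) therefore sits at exactly 0.5 at every purity.
#'
#' @inheritParams expected_log_ratio
#' @param V Variant (mutant) allele copies in the tumor, `0 <= V <= C`;
#'   `V = 0` is the "not in tumor" state.
#' @return Expected allele fraction in \[0, 1\] (vectorised).
#' @examples
#' expected_af_germline(0.7, 2, 1)   # 0.5 regardless of purity
#' expected_af_germline(0.25, 3, 0)  # 1/3: not-in-tumor under CN 3 LOH
#' @export
expected_af_germline <- function(p, C, V) {
  stopifnot(all(p >= 0 & p <= 1), all(V >= 0), all(V <= C))
  (p * V + 1 - p) / (p * C + 2 * (1 - p))
}

#' Expected allele frequency of a clonal somatic variant
#'
#' A somatic variant is absent from normal cells and present on `V` of the
#' `C` tumor copies:
#'
#' \deqn{AF_{somatic} = \frac{pV}{pC + 2(1-p)}}
#'
#' @inheritParams expected_af_germline
#' @examples
#' expected_af_somatic(0.25, 3, 3)  # 1/3: homozygous somatic under CN 3
#' expected_af_somatic(0.5, 2, 1)   # 0.25
#' @export
expected_af_somatic <- function(p, C, V) {
  stopifnot(all(p >= 0 & p <= 1), all(V >= 0), all(V <= C))
  (p * V) / (p * C + 2 * (1 - p))
}

#' Exact two-tailed binomial p-value (minimum-likelihood method)
#'
#' Probability, under `X ~ Binomial(n, q)`, of any outcome no more likely
#' than the observed count: `p = sum over j of P(X = j)` for all `j` with
#' `P(X = j) <= P(X = k) * (1 + 1e-7)`. The relative slack guards against
#' floating-point ties between the two tails.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param q Success probability under the null.
#' @return p-value in (0, 1].
#' @examples
#' two_tailed_binomial_p(5, 10, 0.5)  # 1: the mode itself
#' two_tailed_binomial_p(0, 10, 0.5)  # 2/1024
#' @export
two_tailed_binomial_p <- function(k, n, q) {
  stopifnot(length(k) == 1L, k >= 0, k <= n, q >= 0, q <= 1)
  if (q == 0) return(if (k == 0) 1 else 0)
  if (q == 1) return(if (k == n) 1 else 0)
  d <- stats::dbinom(0:n, n, q)
  min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
}
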