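# Somatic / germline / subclonal classification of variants against the
# fitted copy-number model. For a variant in a segment with copy number C
# and minor allele count M at purity p, the candidate variant allele counts
# are V in {M, C-M}; V = 0 (not in tumor) applies to the germline
# hypothesis only. Each hypothesis is scored by an exact two-tailed
# binomial test of the observed alt reads against its expected allele
# frequency, and the four decision rules are applied at level alpha.

sgz_statuses <- c("somatic", "germline", "subclonal_somatic", "ambiguous")
sgz_reasons <- c("none", "high_purity", "model_misfit",
                 "compatible_with_both", "outside_both",
                 "undefined_expectations")

#' Tumor zygosity from variant allele count and copy number
#'
#' @param V Variant allele copies in the tumor, `0 <= V <= C`.
#' @param C Segment copy number.
#' @return `"homozygous"` (all tumor copies mutant), `"heterozygous"`
#'   (some copies), or `"not_in_tumor"` (none). Vectorised.
#' @export
classify_zygosity <- function(V, C) {
  stopifnot(all(V >= 0), all(V <= C))
  dplyr::case_when(
    V == 0 ~ "not_in_tumor",
    V == C ~ "homozygous",
    TRUE ~ "heterozygous"
  )
}

#' Allele-frequency-only comparator (basic method)
#'
#' Classifies a variant as germline when its allele fraction is near 50%
#' or near 100% (within `delta`), otherwise somatic; copy number and purity
#' are ignored and every variant receives a call.
#'
#' @param f Allele fraction in \[0, 1\] (vectorised).
#' @param delta Half-width of the "near" windows.
#' @return Character vector, `"germline"` or `"somatic"`.
#' @export
basic_method_classify <- function(f, delta = 0.10) {
  stopifnot(all(f >= 0 & f <= 1))
  ifelse(abs(f - 0.5) <= delta | f >= 1 - delta, "germline", "somatic")
}

classify_one <- function(chrom, pos, ref, alt, depth, k, f, seg_row, model,
                         alpha, purity_cap, zygosity_min_purity,
                         misfit_sd, subclonal_min_purity) {
  p <- model$purity
  out <- tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt, depth = depth, af = f,
    segment = NA_integer_, C = NA_integer_, M = NA_integer_,
    status = "ambiguous", zygosity = NA_character_, V = NA_integer_,
    af_germline = NA_real_, af_somatic = NA_real_,
    p_germline = NA_real_, p_somatic = NA_real_, reason = "none"
  )
  if (p > purity_cap) {
    out$reason <- "high_purity"
    return(out)
  }
  if (is.null(seg_row)) {
    out$reason <- "model_misfit"
    return(out)
  }
  C <- seg_row$C; M <- seg_row$M
  out$segment <- seg_row$segment
  out$C <- C; out$M <- M
  if (abs(seg_row$median_lr - seg_row$expected_lr) > misfit_sd * seg_row$sd_lr) {
    out$reason <- "model_misfit"
    return(out)
  }
  denom <- p * C + 2 * (1 - p)
  if (denom <= 0) {
    out$reason <- "undefined_expectations"
    return(out)
  }
  v_g <- sort(unique(c(0L, M, C - M)))
  v_s <- sort(setdiff(unique(c(M, C - M)), 0L))
  test_vs <- function(Vs, af_fun) {
    if (length(Vs) == 0) {
      return(list(V = NA_integer_, af = NA_real_, pval = 0))
    }
    afs <- af_fun(p, C, Vs)
    pvs <- vapply(afs, function(q) two_tailed_binomial_p(k, depth, q), 0)
    best <- which(pvs >= max(pvs) - 1e-12)[1]  # ties -> smaller V (sorted)
    list(V = Vs[best], af = afs[best], pval = pvs[best])
  }
  hg <- test_vs(v_g, expected_af_germline)
  hs <- test_vs(v_s, expected_af_somatic)
  out$af_germline <- hg$af
  out$af_somatic <- hs$af
  out$p_germline <- hg$pval
  out$p_somatic <- hs$pval

  if (hs$pval > alpha && hg$pval <= alpha) {
    out$status <- "somatic"; out$V <- hs$V
  } else if (hg$pval > alpha && hs$pval <= alpha) {
    out$status <- "germline"; out$V <- hg$V
  } else if (hg$pval <= alpha && hs$pval <= alpha &&
             !is.na(hs$af) && f < hs$af / 1.5 &&
             p > subclonal_min_purity) {
    out$status <- "subclonal_somatic"
  } else {
    out$reason <- if (hg$pval > alpha && hs$pval > alpha) {
      "compatible_with_both"
    } else {
      "outside_both"
    }
    return(out)
  }
  if (p >= zygosity_min_purity) {
    out$zygosity <- if (out$status == "subclonal_somatic") {
      "subclonal"
    } else {
      classify_zygosity(out$V, C)
    }
  }
  out
}

#' Classify variants as somatic, germline, or subclonal somatic
#'
#' The core decision engine. Each variant's observed alt-read count
#' (`round(depth * af)`, or the exact `alt_depth` when present) is tested
#' against the germline and somatic expected allele frequencies of its
#' segment with exact two-tailed binomial tests, taking for each hypothesis
#' the candidate allele count V maximizing the p-value. Decision rules at
#' level `alpha`:
#'
#' * somatic: `P(y|S) > alpha` and `P(y|G) <= alpha`;
#' * germline: `P(y|G) > alpha` and `P(y|S) <= alpha`;
#' * subclonal somatic: both `<= alpha`, `f < AF_somatic / 1.5`, and purity
#'   above `subclonal_min_purity`;
#' * otherwise ambiguous, with the no-call reason recorded.
#'
#' No-call gates: specimens with model purity above `purity_cap` are not
#' called (`high_purity`); variants in segments where the model grossly
#' misfits the observed log-ratio (beyond `misfit_sd` segment SDs), or
#' outside any modeled segment, are `model_misfit`. Zygosity is reported
#' only at purity `>= zygosity_min_purity`.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, `depth`, `af`
#'   (and optionally `alt_depth`).
#' @param model Selected `sgz_cn_model`.
#' @param alpha Significance level of the binomial tests (default 0.01).
#' @param purity_cap No-call purity gate (default 0.95).
#' @param zygosity_min_purity Minimum purity for zygosity calls (0.20).
#' @param subclonal_min_purity Minimum purity for subclonal calls (0.20).
#' @param misfit_sd Model-misfit threshold in segment log-ratio SDs.
#' @return Tibble of calls (class `sgz_calls`): input columns plus
#'   `segment`, `C`, `M`, `status`, `zygosity`, `V`, `af_germline`,
#'   `af_somatic`, `p_germline`, `p_somatic`, `reason`.
#' @export
classify_variants <- function(variants, model, alpha = 0.01,
                              purity_cap = 0.95, zygosity_min_purity = 0.20,
                              subclonal_min_purity = 0.20, misfit_sd = 3) {
  stopifnot(inherits(model, "sgz_cn_model"),
            all(c("chrom", "pos", "depth", "af") %in% names(variants)))
  if (!"ref" %in% names(variants)) variants$ref <- NA_character_
  if (!"alt" %in% names(variants)) variants$alt <- NA_character_
  seg <- model$segments
  n <- nrow(variants)
  k <- if ("alt_depth" %in% names(variants)) {
    as.integer(variants$alt_depth)
  } else {
    as.integer(round(variants$depth * variants$af))
  }
  calls <- purrr::map(seq_len(n), function(i) {
    srow <- assign_segment(variants$chrom[i], variants$pos[i], seg)
    classify_one(variants$chrom[i], variants$pos[i], variants$ref[i],
                 variants$alt[i], variants$depth[i], k[i], variants$af[i],
                 srow, model, alpha, purity_cap, zygosity_min_purity,
                 misfit_sd, subclonal_min_purity)
  })
  out <- dplyr::bind_rows(calls)
  class(out) <- c("sgz_calls", class(out))
  attr(out, "purity") <- model$purity
  attr(out, "alpha") <- alpha
  out
}

# nearest segment on the variant's chromosome (by midpoint distance when
# the position falls outside every segment); NULL if the chromosome is
# unmodeled
assign_segment <- function(chrom, pos, seg) {
  rows <- which(seg$chrom == chrom)
  if (length(rows) == 0) return(NULL)
  inside <- rows[pos >= seg$start[rows] & pos < seg$end[rows]]
  if (length(inside)) return(seg[inside[1], ])
  mid <- (seg$start[rows] + seg$end[rows]) / 2
  seg[rows[which.min(abs(pos - mid))], ]
}
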