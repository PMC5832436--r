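#' Circular binary segmentation of a log-ratio profile
#'
#' Recursively partitions each chromosome into segments of homogeneous
#' log-ratio. At each step the arc maximizing the two-sample t statistic
#' between arc and complement is found; the split is accepted if its
#' permutation p-value falls below `cbs_alpha`, and the resulting pieces
#' are segmented recursively. Splits that would create a segment shorter
#' than `min_bins` bins are never proposed, so a 12-bin chromosome with the
#' default `min_bins = 10` is always a single segment.
#'
#' @param profile Log-ratio profile from [compute_log_ratio()] /
#'   [gc_correct()].
#' @param cbs_alpha Permutation significance level for accepting a split.
#' @param n_perm Permutations per test (early-terminated once the decision
#'   is determined).
#' @param min_bins Minimum segment length in bins.
#' @param seed Optional seed for the permutation RNG stream, making
#'   boundaries reproducible.
#' @return Tibble of segment boundaries: `chrom`, `start`, `end`, `n_bins`.
#' @export
cbs_segment <- function(profile, cbs_alpha = 0.01, n_perm = 1000L,
                        min_bins = 10L, seed = NULL) {
  stopifnot(nrow(profile) >= 1)
  local_seed(seed, {
    profile <- dplyr::arrange(profile,
                              match(.data$chrom, unique(profile$chrom)),
                              .data$start)
    out <- profile |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_map(function(d, key) {
        bounds <- cbs_recurse(d$log_ratio, cbs_alpha, n_perm, min_bins)
        tibble::tibble(
          chrom = key$chrom[[1]],
          start = d$start[bounds$from],
          end = d$end[bounds$to],
          n_bins = bounds$to - bounds$from + 1L
        )
      }) |>
      dplyr::bind_rows()
    out[order(match(out$chrom, unique(profile$chrom)), out$start), ]
  })
}

# Recursive CBS on one chromosome; returns 1-based [from, to] bin ranges.
cbs_recurse <- function(x, alpha, n_perm, min_bins, offset = 0L) {
  n <- length(x)
  leaf <- tibble::tibble(from = offset + 1L, to = offset + n)
  if (n < 2L * min_bins) return(leaf)
  res <- .cbs_test(x, as.integer(min_bins), as.integer(n_perm), alpha)
  if (is.na(res$i) || res$p >= alpha) return(leaf)
  i <- res$i; j <- res$j  # arc is x[(i+1)..j], 0-based half-open [i, j)
  pieces <- list(c(1L, i), c(i + 1L, j), c(j + 1L, n))
  pieces <- purrr::keep(pieces, ~ .x[2] >= .x[1])
  dplyr::bind_rows(purrr::map(pieces, function(pc) {
    cbs_recurse(x[pc[1]:pc[2]], alpha, n_perm, min_bins,
                offset = offset + pc[1] - 1L)
  }))
}

#' Attach summary statistics to segments
#'
#' For each segment computes the median and SD of its bin log-ratios and
#' the mean and SD of the folded minor allele fractions of the het SNPs it
#' contains. SDs are floored (`sd_floor_lr`, `sd_floor_maf`) so tiny
#' segments cannot collapse the model likelihood with a zero variance.
#'
#' @param segments Boundary tibble from [cbs_segment()].
#' @param profile Log-ratio profile used for segmentation.
#' @param maf Het-SNP profile from [select_het_snps()] (may be empty).
#' @param sd_floor_lr,sd_floor_maf Lower bounds on the SDs (log2 units /
#'   fraction).
#' @return Tibble with one row per segment: `segment`, `chrom`, `start`,
#'   `end`, `n_bins`, `median_lr`, `sd_lr`, `n_snps`, `mean_maf`, `sd_maf`,
#'   `mean_snp_depth`. MAF columns are `NA` for segments without SNPs.
#' @export
summarize_segments <- function(segments, profile, maf = NULL,
                               sd_floor_lr = 0.05, sd_floor_maf = 0.02) {
  if (is.null(maf)) {
    maf <- tibble::tibble(chrom = character(), pos = integer(),
                          depth = integer(), af = double(), maf = double())
  }
  res <- purrr::pmap(
    list(segments$chrom, segments$start, segments$end),
    function(ch, s, e) {
      lr <- profile$log_ratio[profile$chrom == ch &
                                profile$start >= s & profile$start < e]
      mm <- maf[maf$chrom == ch & maf$pos >= s & maf$pos < e, ]
      tibble::tibble(
        n_bins = length(lr),
        median_lr = stats::median(lr),
        sd_lr = max(sd_floor_lr,
                    if (length(lr) > 1) stats::sd(lr) else 0),
        n_snps = nrow(mm),
        mean_maf = if (nrow(mm) > 0) mean(mm$maf) else NA_real_,
        sd_maf = if (nrow(mm) > 1) max(sd_floor_maf, stats::sd(mm$maf))
                 else if (nrow(mm) == 1) sd_floor_maf else NA_real_,
        mean_snp_depth = if (nrow(mm) > 0) mean(mm$depth) else NA_real_
      )
    }
  )
  dplyr::bind_cols(
    tibble::tibble(segment = seq_len(nrow(segments)),
                   chrom = segments$chrom, start = segments$start,
                   end = segments$end),
    dplyr::bind_rows(res)
  )
}
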