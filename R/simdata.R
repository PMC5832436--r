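#' Default synthetic tumor genome
#'
#' A 20-segment, 8-chromosome aneuploid genome covering the copy-number
#' states the classifier must distinguish: copy-neutral balanced segments
#' (C = 2, M = 1), copy-neutral LOH (C = 2, M = 0), single-copy losses
#' (C = 1), gains with and without allelic imbalance (C = 3 and 4), and a
#' focal C = 5 amplification. Consecutive segments within a chromosome
#' always differ in total copy number so that every true breakpoint is
#' visible in the log-ratio profile.
#'
#' @param n_bins Bins per segment (uniform).
#' @return A tibble with columns `chrom`, `n_bins`, `C`, `M`.
#' @export
sim_genome_default <- function(n_bins = 80) {
  g <- tibble::tribble(
    ~chrom, ~C, ~M,
    "chr1", 2L, 1L, "chr1", 3L, 1L, "chr1", 2L, 0L,
    "chr2", 2L, 1L, "chr2", 1L, 0L, "chr2", 2L, 1L,
    "chr3", 4L, 2L, "chr3", 2L, 1L, "chr3", 3L, 0L,
    "chr4", 2L, 0L, "chr4", 3L, 1L,
    "chr5", 2L, 1L, "chr5", 4L, 1L, "chr5", 2L, 1L,
    "chr6", 1L, 0L, "chr6", 2L, 1L,
    "chr7", 3L, 1L, "chr7", 2L, 1L,
    "chr8", 2L, 1L, "chr8", 5L, 2L
  )
  g$n_bins <- as.integer(n_bins)
  g[, c("chrom", "n_bins", "C", "M")]
}

#' Default variant panel for a simulated specimen
#'
#' Distributes germline and clonal somatic variants over the segments of a
#' genome table. A variant rides one parental lineage, so its tumor allele
#' count is drawn from \{M, C - M\}: for germline variants either count
#' (including 0, the allele lost to LOH); for somatic variants the non-zero
#' ones. Homozygous somatic variants (V = C) arise naturally in LOH
#' segments (M = 0).
#'
#' @param genome Segment table as from [sim_genome_default()].
#' @param n_germline,n_somatic Variant counts.
#' @param seed Integer seed.
#' @return A tibble with columns `segment`, `origin`, `V`, `ccf`.
#' @export
sim_variants_default <- function(genome, n_germline = 20, n_somatic = 20,
                                 seed = NULL) {
  local_seed(seed, {
    nseg <- nrow(genome)
    seg_g <- sample.int(nseg, n_germline, replace = TRUE)
    seg_s <- sample.int(nseg, n_somatic, replace = TRUE)
    v_g <- purrr::map_int(seg_g, function(i) {
      cand <- unique(c(genome$M[i], genome$C[i] - genome$M[i]))
      sample(rep(cand, 2), 1)
    })
    v_s <- purrr::map_int(seg_s, function(i) {
      cand <- setdiff(unique(c(genome$M[i], genome$C[i] - genome$M[i])), 0L)
      if (length(cand) == 0) NA_integer_ else sample(rep(cand, 2), 1)
    })
    keep_s <- !is.na(v_s)  # C = 0 segments cannot host a somatic variant
    dplyr::bind_rows(
      tibble::tibble(segment = seg_g, origin = "germline", V = v_g, ccf = 1),
      tibble::tibble(segment = seg_s[keep_s], origin = "somatic",
                     V = v_s[keep_s], ccf = 1)
    )
  })
}

#' Simulation configuration for one synthetic specimen
#'
#' Bundles the ground truth (purity, segment copy-number states, variant
#' origins) and the observation model (sequencing depth, log-ratio noise,
#' SNP panel density) for [simulate_specimen()].
#'
#' The observation model mirrors deep targeted sequencing of an admixed
#' tumor: per-bin normal depth is Poisson around `mean_depth`; tumor depth
#' is Poisson around `mean_depth * 2^(expected log-ratio)` with additional
#' log-normal bin noise of SD `lr_noise_sd` (log2 units); SNP and variant
#' alt reads are binomial at the model-expected allele fractions.
#'
#' @param purity Tumor purity in \[0, 1\].
#' @param genome Segment table (`chrom`, `n_bins`, `C`, `M`); defaults to
#'   [sim_genome_default()].
#' @param variants Variant table (`segment`, `origin`, `V`, `ccf`); `ccf` is
#'   the cancer-cell fraction (1 = clonal). Default [sim_variants_default()].
#' @param mean_depth Mean sequencing depth per bin/site.
#' @param lr_noise_sd Per-bin multiplicative coverage noise, SD in log2 units.
#' @param snps_per_segment Genome-wide SNP panel density.
#' @param het_snp_fraction Fraction of panel SNPs heterozygous in the patient.
#' @param gc_bias Optional polynomial coefficients (intercept first) of a
#'   multiplicative GC bias applied to tumor depth.
#' @param bin_width Bin width in bp (coordinates are synthetic, 0-based
#'   half-open).
#' @param seed Integer seed; same seed and config give identical specimens.
#' @return An object of class `sgz_sim_config` (a named list).
#' @export
sim_config <- function(purity,
                       genome = sim_genome_default(),
                       variants = NULL,
                       mean_depth = 800,
                       lr_noise_sd = 0.1,
                       snps_per_segment = 30,
                       het_snp_fraction = 0.6,
                       gc_bias = NULL,
                       bin_width = 1000L,
                       seed = 1L) {
  stopifnot(purity >= 0, purity <= 1, mean_depth > 0, lr_noise_sd >= 0,
            het_snp_fraction >= 0, het_snp_fraction <= 1,
            all(genome$n_bins >= 1), all(genome$C >= 0),
            all(genome$M >= 0), all(2 * genome$M <= genome$C))
  if (is.null(variants)) {
    variants <- sim_variants_default(genome, seed = seed)
  }
  validate_variant_spec(variants, genome)
  structure(
    list(purity = purity, genome = genome, variants = variants,
         mean_depth = mean_depth, lr_noise_sd = lr_noise_sd,
         snps_per_segment = snps_per_segment,
         het_snp_fraction = het_snp_fraction, gc_bias = gc_bias,
         bin_width = as.integer(bin_width), seed = as.integer(seed)),
    class = "sgz_sim_config"
  )
}

validate_variant_spec <- function(variants, genome) {
  stopifnot(all(c("segment", "origin", "V", "ccf") %in% names(variants)))
  if (nrow(variants) == 0) return(invisible(TRUE))
  stopifnot(all(variants$origin %in% c("germline", "somatic")),
            all(variants$segment >= 1),
            all(variants$segment <= nrow(genome)),
            all(variants$ccf > 0), all(variants$ccf <= 1))
  C <- genome$C[variants$segment]
  bad <- variants$V > C | variants$V < 0 |
    (variants$origin == "somatic" & variants$V < 1)
  if (any(bad)) {
    stop("inconsistent variant_spec: V must satisfy 0 <= V <= C ",
         "(>= 1 for somatic); offending rows: ",
         paste(which(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Simulate one tumor specimen with known truth
#'
#' Generates per-bin tumor/normal coverage, genome-wide SNP allele depths,
#' and candidate variants for a specimen of known purity, ploidy, and
#' per-segment copy-number state. The generative means are the model
#' expectations: bin log-ratios center on
#' `log2((pC + 2(1-p)) / (p*psi + 2(1-p)))`, heterozygous SNP allele
#' fractions on `(pM + 1-p)/(pC + 2(1-p))` (randomly oriented to either
#' parental allele), germline variant alt reads are
#' `Binomial(n, (pV + 1-p)/(pC + 2(1-p)))` and somatic alt reads
#' `Binomial(n, ccf * pV/(pC + 2(1-p)))` (subclonality thins the tumor
#' numerator). Homozygous panel SNPs are emitted at alt fraction 0.999 so
#' heterozygous-SNP selection has realistic work to do.
#'
#' @param config An [sim_config()] object.
#' @return An `sgz_specimen`: list with tibbles `bins` (chrom, start, end,
#'   gc, tumor_depth, normal_depth), `snps` (chrom, pos, depth, alt_depth),
#'   `variants` (chrom, pos, ref, alt, depth, alt_depth, af), and `truth`
#'   (list: purity, ploidy, segments, variants).
#' @export
simulate_specimen <- function(config) {
  stopifnot(inherits(config, "sgz_sim_config"))
  local_seed(config$seed, simulate_specimen_impl(config))
}

simulate_specimen_impl <- function(config) {
  g <- config$genome
  p <- config$purity
  psi <- compute_ploidy(g$n_bins, g$C)
  elr <- expected_log_ratio(p, g$C, psi)
  emaf <- expected_maf(p, g$C, g$M)
  bw <- config$bin_width

  # segment coordinates: sequential bins per chromosome
  g2 <- g |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(bin0 = cumsum(dplyr::lag(.data$n_bins, default = 0L))) |>
    dplyr::ungroup() |>
    dplyr::mutate(segment = dplyr::row_number(),
                  start = .data$bin0 * bw,
                  end = (.data$bin0 + .data$n_bins) * bw)

  seg_of_bin <- rep(g2$segment, g2$n_bins)
  bin_in_seg <- unlist(lapply(g2$n_bins, seq_len)) - 1L
  bins <- tibble::tibble(
    chrom = g2$chrom[seg_of_bin],
    start = g2$start[seg_of_bin] + bin_in_seg * bw,
    end = g2$start[seg_of_bin] + (bin_in_seg + 1L) * bw,
    gc = stats::runif(length(seg_of_bin), 0.3, 0.65)
  )
  mu_t <- config$mean_depth *
    2^(elr[seg_of_bin] + stats::rnorm(nrow(bins), 0, config$lr_noise_sd))
  if (!is.null(config$gc_bias)) {
    gcfac <- drop(outer(bins$gc, seq_along(config$gc_bias) - 1, `^`) %*%
                    config$gc_bias)
    mu_t <- mu_t * pmax(gcfac, 0.05)
  }
  bins$tumor_depth <- stats::rpois(nrow(bins), mu_t)
  bins$normal_depth <- stats::rpois(nrow(bins), config$mean_depth)

  # genome-wide SNP panel
  nsnp <- config$snps_per_segment
  snp_seg <- rep(g2$segment, nsnp)
  snp_pos <- g2$start[snp_seg] +
    floor(stats::runif(length(snp_seg)) * (g2$end - g2$start)[snp_seg])
  snp_depth <- stats::rpois(length(snp_seg),
                            config$mean_depth * 2^elr[snp_seg])
  is_het <- stats::runif(length(snp_seg)) < config$het_snp_fraction
  flip <- stats::runif(length(snp_seg)) < 0.5
  q_het <- ifelse(flip, emaf[snp_seg], 1 - emaf[snp_seg])
  q <- ifelse(is_het, q_het, 0.999)
  snps <- tibble::tibble(
    chrom = g2$chrom[snp_seg], pos = snp_pos, depth = snp_depth,
    alt_depth = stats::rbinom(length(snp_seg), snp_depth, q)
  ) |> dplyr::arrange(.data$chrom, .data$pos)

  # candidate variants
  v <- config$variants
  truth_variants <- NULL
  variants <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), depth = integer(), alt_depth = integer(),
    af = double()
  )
  if (nrow(v) > 0) {
    vseg <- v$segment
    pos <- g2$start[vseg] +
      floor(stats::runif(nrow(v)) * (g2$end - g2$start)[vseg])
    while (anyDuplicated(paste(g2$chrom[vseg], pos))) {
      d <- duplicated(paste(g2$chrom[vseg], pos))
      pos[d] <- g2$start[vseg[d]] +
        floor(stats::runif(sum(d)) * (g2$end - g2$start)[vseg[d]])
    }
    n <- stats::rpois(nrow(v), config$mean_depth * 2^elr[vseg])
    denom <- p * g2$C[vseg] + 2 * (1 - p)
    qv <- ifelse(v$origin == "germline",
                 (p * v$V + 1 - p) / denom,
                 v$ccf * p * v$V / denom)
    alt_reads <- stats::rbinom(nrow(v), n, qv)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(v), replace = TRUE)
    altb <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
    variants <- tibble::tibble(
      chrom = g2$chrom[vseg], pos = as.integer(pos), ref = ref, alt = altb,
      depth = n, alt_depth = alt_reads,
      af = ifelse(n > 0, alt_reads / n, NA_real_)
    )
    truth_variants <- variants |>
      dplyr::select("chrom", "pos", "ref", "alt") |>
      dplyr::mutate(segment = vseg, origin = v$origin, V = v$V,
                    ccf = v$ccf, expected_af = qv,
                    C = g2$C[vseg], M = g2$M[vseg])
    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, ]
    truth_variants <- truth_variants[ord, ]
  }

  structure(
    list(
      bins = bins, snps = snps, variants = variants,
      truth = list(
        purity = p, ploidy = psi,
        segments = g2 |>
          dplyr::select("segment", "chrom", "start", "end", "n_bins",
                        "C", "M") |>
          dplyr::mutate(expected_lr = elr, expected_maf = emaf),
        variants = truth_variants
      ),
      config = config
    ),
    class = "sgz_specimen"
  )
}

#' @export
print.sgz_specimen <- function(x, ...) {
  cat("<sgz_specimen>\n")
  cat(sprintf("  truth: purity %.2f, ploidy %.2f, %d segments\n",
              x$truth$purity, x$truth$ploidy, nrow(x$truth$segments)))
  cat(sprintf("  %d bins, %d SNPs, %d candidate variants\n",
              nrow(x$bins), nrow(x$snps), nrow(x$variants)))
  invisible(x)
}

#' Simulate a purity-titration cohort
#'
#' Generates `n_specimens` specimens sharing a genome and variant panel but
#' differing in tumor purity, mirroring a cell-line titration series mixed
#' with its matched normal at fixed proportions. Per-specimen seeds are
#' derived deterministically from `seed`.
#'
#' @param config_template An [sim_config()]; its purity is overridden.
#' @param n_specimens Number of specimens.
#' @param purities Either a length-2 range (purities are spaced evenly
#'   across it) or a vector of exactly `n_specimens` purities, e.g. the
#'   six-level titration `c(0.10, 0.20, 0.30, 0.40, 0.50, 0.75)`.
#' @param seed Master seed.
#' @return List of `sgz_specimen` objects.
#' @export
simulate_cohort <- function(config_template, n_specimens,
                            purities = c(0.2, 0.8), seed = 1L) {
  stopifnot(n_specimens >= 1)
  if (length(purities) == 0) stop("empty purity range")
  pur <- if (length(purities) == n_specimens) {
    purities
  } else if (length(purities) == 2L) {
    seq(purities[1], purities[2], length.out = n_specimens)
  } else {
    stop("`purities` must be a range of length 2 or one purity per specimen")
  }
  seeds <- derive_seeds(seed, n_specimens)
  purrr::map2(pur, seeds, function(p, s) {
    cfg <- config_template
    cfg$purity <- p
    cfg$seed <- s
    simulate_specimen(cfg)
  })
}
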