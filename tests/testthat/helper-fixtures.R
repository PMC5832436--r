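# Shared fixtures: compact genomes and hand-built segment tables keep the
# unit tests fast while the acceptance tests use the full-size defaults.

small_genome <- function(n_bins = 30) {
  tibble::tribble(
    ~chrom, ~C, ~M,
    "chr1", 2L, 1L, "chr1", 3L, 1L,
    "chr2", 2L, 0L, "chr2", 1L, 0L,
    "chr3", 4L, 2L, "chr3", 2L, 1L,
    "chr4", 3L, 0L, "chr4", 2L, 1L
  ) |>
    dplyr::mutate(n_bins = as.integer(n_bins), .after = "chrom")
}

# noise-free segment summary at known truth (observations set exactly to
# the model expectations, folded at the given SNP depth)
exact_segments <- function(purity, genome, depth = 800, n_snps = 30) {
  psi <- compute_ploidy(genome$n_bins, genome$C)
  emaf <- expected_maf(purity, genome$C, genome$M)
  tibble::tibble(
    segment = seq_len(nrow(genome)),
    chrom = genome$chrom,
    start = (seq_len(nrow(genome)) - 1L) * 1000L,
    end = seq_len(nrow(genome)) * 1000L,
    n_bins = genome$n_bins,
    median_lr = expected_log_ratio(purity, genome$C, psi),
    sd_lr = 0.05,
    n_snps = n_snps,
    mean_maf = sgzr:::expected_folded_maf(
      emaf, sqrt(emaf * (1 - emaf) / depth)),
    sd_maf = 0.02,
    mean_snp_depth = depth
  )
}

# single-segment copy-number model for exercising the decision engine
toy_model <- function(purity, C, M, median_lr = NULL, sd_lr = 0.05,
                      psi0 = NULL) {
  psi0 <- psi0 %||% max(C, 1)
  seg <- tibble::tibble(
    segment = 1L, chrom = "chr1", start = 0L, end = 100000L,
    n_bins = 100L,
    median_lr = median_lr %||% expected_log_ratio(purity, C, psi0),
    sd_lr = sd_lr, n_snps = 30L, mean_maf = expected_maf(purity, C, M),
    sd_maf = 0.02, mean_snp_depth = 800
  )
  sgzr:::new_cn_model(purity, psi0, C, M, seg, source = "grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive minimum-likelihood two-tailed binomial p-value (oracle)
enum_binom_p <- function(k, n, q) {
  d <- dbinom(0:n, n, q)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}
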