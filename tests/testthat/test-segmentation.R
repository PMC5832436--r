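flat_profile <- function(n, chrom = "chr1", level = 0, sd = 0, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    chrom = chrom, start = (seq_len(n) - 1L) * 1000L,
    end = seq_len(n) * 1000L, gc = 0.5,
    log_ratio = level + rnorm(n, 0, sd)
  )
}

test_that("a homogeneous chromosome stays one segment", {
  p <- flat_profile(120, sd = 0.1, seed = 3)
  b <- cbs_segment(p, seed = 5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_bins, 120L)
})

test_that("a 1.0 log2 step is found within two bins", {
  p <- dplyr::bind_rows(flat_profile(200, level = 0, sd = 0.1, seed = 4),
                        flat_profile(200, level = 1, sd = 0.1, seed = 5)) |>
    dplyr::mutate(start = (dplyr::row_number() - 1L) * 1000L,
                  end = dplyr::row_number() * 1000L)
  b <- cbs_segment(p, seed = 6)
  expect_equal(nrow(b), 2L)
  expect_lte(abs(b$start[2] / 1000 - 200), 2)
})

test_that("chromosomes shorter than twice min_bins are never split", {
  p <- dplyr::bind_rows(flat_profile(6, level = 0), flat_profile(6, level = 3)) |>
    dplyr::mutate(start = (dplyr::row_number() - 1L) * 1000L,
                  end = dplyr::row_number() * 1000L)
  b <- cbs_segment(p, min_bins = 10, seed = 2)
  expect_equal(nrow(b), 1L)
})

test_that("noise-free breakpoints are recovered exactly", {
  lv <- rep(c(0, 0.8, -0.5), times = c(40, 30, 50))
  p <- flat_profile(120, sd = 0) |> dplyr::mutate(log_ratio = lv)
  b <- cbs_segment(p, seed = 9)
  expect_equal(b$start / 1000, c(0, 40, 70))
  expect_equal(b$n_bins, c(40L, 30L, 50L))
})

test_that("segmentation is reproducible under a fixed seed and partitions the bins", {
  sp <- simulate_specimen(sim_config(0.5, genome = small_genome(40), seed = 41))
  prof <- compute_log_ratio(sp$bins)
  b1 <- cbs_segment(prof, seed = 10)
  b2 <- cbs_segment(prof, seed = 10)
  expect_identical(b1, b2)
  expect_equal(sum(b1$n_bins), nrow(prof))
  # disjoint and exhaustive within each chromosome
  for (ch in unique(b1$chrom)) {
    sub <- b1[b1$chrom == ch, ]
    expect_true(all(sub$start[-1] == sub$end[-nrow(sub)]))
  }
  expect_gte(nrow(b1), length(unique(prof$chrom)))
  expect_lte(nrow(b1), nrow(prof) / 10)
})

test_that("segment summaries carry medians, floored SDs, and SNP statistics", {
  p <- flat_profile(500, level = 0.5, sd = 0.1, seed = 12)
  b <- tibble::tibble(chrom = "chr1", start = 0L, end = 500000L,
                      n_bins = 500L)
  s <- summarize_segments(b, p, NULL)
  expect_lt(abs(s$median_lr - 0.5), 0.03)
  expect_lt(abs(s$sd_lr - 0.1), 0.03)
  expect_equal(s$n_snps, 0L)
  expect_true(is.na(s$mean_maf))
  # single-bin segment gets the SD floor
  s1 <- summarize_segments(
    tibble::tibble(chrom = "chr1", start = 0L, end = 1000L, n_bins = 1L),
    p[1, ], NULL)
  expect_equal(s1$sd_lr, 0.05)
  # SNPs are attached by interval
  maf <- tibble::tibble(chrom = "chr1", pos = c(5L, 999999L),
                        depth = c(100L, 100L), af = c(0.4, 0.4),
                        maf = c(0.4, 0.4))
  s2 <- summarize_segments(b, p, maf)
  expect_equal(s2$n_snps, 1L)
  expect_equal(s2$mean_maf, 0.4)
})
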