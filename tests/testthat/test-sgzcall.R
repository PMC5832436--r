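test_that("zygosity follows the allele-count definition", {
  expect_equal(classify_zygosity(3, 3), "homozygous")
  expect_equal(classify_zygosity(1, 2), "heterozygous")
  expect_equal(classify_zygosity(0, 2), "not_in_tumor")
  expect_equal(classify_zygosity(c(0, 1, 4), c(4, 4, 4)),
               c("not_in_tumor", "heterozygous", "homozygous"))
})

test_that("the AF-only basic method uses the near-50%/near-100% windows", {
  expect_equal(basic_method_classify(0.50), "germline")
  expect_equal(basic_method_classify(0.25), "somatic")
  expect_equal(basic_method_classify(0.95), "germline")
  expect_equal(basic_method_classify(0.60), "germline")  # boundary: |f-.5| = .1
  expect_equal(basic_method_classify(0.61), "somatic")
  expect_equal(basic_method_classify(c(0, 1)), c("somatic", "germline"))
})

mk_variant <- function(n, f, pos = 50000L) {
  tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                 depth = as.integer(n), af = f)
}

test_that("classification reproduces the binomial decision rules", {
  # diploid balanced segment at purity 0.3: germline het sits at 0.5,
  # somatic het at 0.15
  m <- toy_model(0.3, 2L, 1L, psi0 = 2)
  g <- classify_variants(mk_variant(500, 0.5), m)
  expect_equal(g$status, "germline")
  expect_equal(g$zygosity, "heterozygous")
  expect_equal(g$V, 1L)
  expect_equal(g$af_germline, 0.5)
  expect_equal(g$p_germline, binom.test(250, 500, 0.5)$p.value)
  expect_lte(g$p_somatic, 0.01)

  s <- classify_variants(mk_variant(500, 0.15), m)
  expect_equal(s$status, "somatic")
  expect_equal(s$zygosity, "heterozygous")
  expect_equal(s$af_somatic, expected_af_somatic(0.3, 2, 1))
  expect_equal(s$p_somatic,
               binom.test(75, 500, expected_af_somatic(0.3, 2, 1))$p.value)

  # subclonal: f far below AF_somatic/1.5 with both hypotheses rejected
  m2 <- toy_model(0.5, 2L, 1L, psi0 = 2)
  sub <- classify_variants(mk_variant(1000, 0.05), m2)
  expect_equal(sub$status, "subclonal_somatic")
  expect_equal(sub$zygosity, "subclonal")
  expect_lt(0.05, sub$af_somatic / 1.5)

  # the CN-3 LOH degeneracy: germline V=0 and somatic V=3 both expect 1/3
  m3 <- toy_model(0.25, 3L, 0L, psi0 = 3)
  amb <- classify_variants(mk_variant(1000, 1 / 3), m3)
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$reason, "compatible_with_both")
  expect_equal(amb$af_germline, amb$af_somatic)
  expect_equal(amb$af_germline, 1 / 3)
})

test_that("no-call gates: high purity, model misfit, unmodeled regions", {
  hp <- toy_model(0.97, 2L, 1L)
  call <- classify_variants(mk_variant(500, 0.5), hp)
  expect_equal(call$status, "ambiguous")
  expect_equal(call$reason, "high_purity")

  # gross log-ratio deviation at the variant's segment
  mis <- toy_model(0.5, 2L, 1L, median_lr = 0.9, psi0 = 2)
  call2 <- classify_variants(mk_variant(500, 0.5), mis)
  expect_equal(call2$reason, "model_misfit")

  # variant on an unmodeled chromosome
  m <- toy_model(0.5, 2L, 1L)
  v <- mk_variant(500, 0.5); v$chrom <- "chrX"
  call3 <- classify_variants(v, m)
  expect_equal(call3$reason, "model_misfit")

  # nearest segment by midpoint when the position is outside all segments
  v2 <- mk_variant(500, 0.5, pos = 900000L)
  call4 <- classify_variants(v2, m)
  expect_equal(call4$status, "germline")
})

test_that("zygosity and subclonal calls honor the purity gates", {
  lowp <- toy_model(0.15, 2L, 1L, psi0 = 2)
  g <- classify_variants(mk_variant(800, 0.5), lowp)
  expect_equal(g$status, "germline")
  expect_true(is.na(g$zygosity))  # zygosity needs purity >= 0.20
  # a frequency far below AF_somatic cannot be called subclonal here
  s <- classify_variants(mk_variant(2000, 0.01), lowp)
  expect_false(identical(s$status, "subclonal_somatic"))
  expect_equal(s$status, "ambiguous")
})

test_that("statuses are exhaustive and ambiguity always carries one reason", {
  sp <- simulate_specimen(sim_config(0.45, genome = small_genome(50), seed = 71))
  segs <- exact_segments(0.45, small_genome(50))
  m <- sgzr:::new_cn_model(0.45, compute_ploidy(segs$n_bins, small_genome()$C),
                           small_genome()$C, small_genome()$M, segs,
                           source = "grid")
  calls <- classify_variants(sp$variants, m)
  expect_true(all(calls$status %in%
                    c("somatic", "germline", "subclonal_somatic", "ambiguous")))
  expect_true(all((calls$status == "ambiguous") == (calls$reason != "none")))
})

test_that("classification depends on the model only through the expected-AF sets", {
  # models that differ in normalization ploidy, unrelated segments, and
  # segment bookkeeping but share the variant segment's (purity, C, M) have
  # identical candidate AF sets, so calls must agree exactly
  set.seed(81)
  for (i in 1:200) {
    p <- runif(1, 0.05, 0.9)
    C <- sample(1:6, 1)
    M <- sample(0:(C %/% 2), 1)
    n <- sample(200:1200, 1)
    f <- runif(1)
    m1 <- toy_model(p, C, M)
    m2 <- toy_model(p, C, M, psi0 = runif(1, 1.5, 4))
    extra <- m2$segments[1, ]
    extra$segment <- 2L; extra$chrom <- "chr9"
    extra$C <- sample(0:6, 1); extra$M <- 0L
    m2$segments <- dplyr::bind_rows(m2$segments, extra)
    v <- mk_variant(n, f)
    c1 <- classify_variants(v, m1)
    c2 <- classify_variants(v, m2)
    cols <- c("status", "zygosity", "p_germline", "p_somatic",
              "af_germline", "af_somatic", "reason")
    expect_identical(c1[, cols], c2[, cols])
  }
})
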