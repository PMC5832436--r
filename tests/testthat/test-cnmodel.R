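test_that("grid fit recovers purity and states exactly on noise-free input", {
  g <- small_genome(50)
  segs <- exact_segments(0.6, g)
  cands <- grid_fit(segs)
  best <- cands[[1]]
  expect_lte(abs(best$purity - 0.6), 0.011)
  expect_equal(best$segments$C, g$C)
  expect_equal(best$segments$M, g$M)
  expect_false(isTRUE(attr(cands, "non_identifiable")))
  # the model invariant: reported ploidy is the length-weighted mean C
  expect_equal(best$ploidy,
               compute_ploidy(best$segments$n_bins, best$segments$C))
})

test_that("a flat balanced genome is flagged non-identifiable", {
  g <- tibble::tibble(chrom = paste0("chr", 1:4), n_bins = 50L,
                      C = 2L, M = 1L)
  cands <- grid_fit(exact_segments(0.5, g))
  expect_true(attr(cands, "non_identifiable"))
})

test_that("a single segment degenerates and is flagged", {
  g <- tibble::tibble(chrom = "chr1", n_bins = 50L, C = 2L, M = 1L)
  segs <- exact_segments(0.5, g)
  segs$median_lr <- 0  # median normalization forces a lone segment to 0
  m <- fit_copy_number(segs, use_mcmc = FALSE)
  expect_true("non_identifiable" %in% m$flags)
})

test_that("model scoring matches brute-force arithmetic and penalizes wrong C", {
  g <- tibble::tibble(chrom = c("chr1", "chr2"), n_bins = c(30L, 10L),
                      C = c(2L, 3L), M = c(1L, 1L))
  segs <- exact_segments(0.5, g)
  truth <- sgzr:::new_cn_model(0.5, compute_ploidy(g$n_bins, g$C),
                               g$C, g$M, segs, source = "grid")
  sc <- score_model(truth, segs)
  expect_equal(unname(sc["mse_lr"]), 0, tolerance = 1e-12)
  expect_equal(unname(sc["mse_maf"]), 0, tolerance = 1e-12)
  # brute-force check of the weighting on a perturbed model
  pert <- sgzr:::new_cn_model(0.5, truth$psi0, c(3L, 3L), g$M, segs,
                              source = "grid")
  elr <- expected_log_ratio(0.5, 3, truth$psi0)
  by_hand <- (30 * (segs$median_lr[1] - elr)^2 + 10 * 0) / 40
  expect_equal(pert$mse_lr, by_hand)
  expect_gt(pert$mse_lr, truth$mse_lr)
})

test_that("MCMC fit recovers truth, converges, and is deterministic", {
  g <- small_genome(60)
  set.seed(51)
  segs <- exact_segments(0.5, g)
  # small observation noise so the posterior has realistic width
  segs$median_lr <- segs$median_lr + rnorm(nrow(segs), 0, 0.005)
  segs$mean_maf <- segs$mean_maf + rnorm(nrow(segs), 0, 0.002)
  m <- mcmc_fit(segs, seed = 52)
  expect_lte(abs(m$purity - 0.5), 0.02)
  expect_equal(m$segments$C, g$C)
  expect_equal(m$segments$M, g$M)
  expect_lte(m$rhat, 1.1)   # dispersed chains agree
  m2 <- mcmc_fit(segs, seed = 52)
  expect_identical(m$draws, m2$draws)
  expect_equal(m$purity, m2$purity)
  # grid and MCMC agree: same states, purity within one grid step
  best <- grid_fit(segs)[[1]]
  expect_equal(best$segments$C, m$segments$C)
  expect_lte(abs(best$purity - m$purity), 0.011)
})

test_that("five-requirement selection accepts and rejects candidates as specified", {
  g <- small_genome(50)
  segs <- exact_segments(0.55, g)
  psi <- compute_ploidy(g$n_bins, g$C)
  gibbs <- sgzr:::new_cn_model(0.55, psi, g$C, g$M, segs, source = "gibbs")
  gibbs$score <- 0.05
  # nudge the gibbs model off the optimum so a candidate can reduce MSEs
  gibbs$segments$C[1] <- gibbs$segments$C[1] + 1L
  mse <- score_model(gibbs, segs)
  gibbs$mse_lr <- mse[["mse_lr"]]; gibbs$mse_maf <- mse[["mse_maf"]]

  good <- sgzr:::new_cn_model(0.55, psi, g$C, g$M, segs, source = "grid")
  good$score <- 0.001
  sel <- select_model(gibbs, list(good), segs)
  expect_equal(sel$source, "grid")
  expect_equal(sel$segments$C, g$C)

  # rule 2: ploidy must exceed 1.2
  low_pl <- sgzr:::new_cn_model(
    0.55, 1.1, rep(1L, nrow(g)), rep(0L, nrow(g)), segs, source = "grid")
  low_pl$score <- 0; low_pl$mse_lr <- 0; low_pl$mse_maf <- 0
  sel2 <- select_model(gibbs, list(low_pl), segs)
  expect_equal(sel2$purity, gibbs$purity)
  expect_equal(sel2$source, "gibbs")

  # rule 4: genome-doubled-style candidates (higher ploidy, lower purity)
  dbl <- sgzr:::new_cn_model(0.40, 2 * psi, 2L * g$C, 2L * g$M, segs,
                             source = "grid")
  dbl$score <- 0; dbl$mse_lr <- 0; dbl$mse_maf <- 0
  sel3 <- select_model(gibbs, list(dbl), segs)
  expect_equal(sel3$source, "gibbs")

  # rule 5: near-pure candidates need the independent high-purity screen
  hp <- sgzr:::new_cn_model(1, psi, g$C, g$M, segs, source = "grid")
  hp$score <- 0; hp$mse_lr <- 0; hp$mse_maf <- 0
  sel4 <- select_model(gibbs, list(hp), segs, high_purity_ok = FALSE)
  expect_equal(sel4$source, "gibbs")
  sel5 <- select_model(gibbs, list(hp), segs, high_purity_ok = TRUE)
  expect_equal(sel5$purity, 1)

  # rule 3: excessive copy-number loss disqualifies
  loss <- sgzr:::new_cn_model(0.55, psi, c(0L, 0L, g$C[-(1:2)]),
                              c(0L, 0L, g$M[-(1:2)]), segs, source = "grid")
  loss$score <- 0; loss$mse_lr <- 0; loss$mse_maf <- 0
  expect_true("excessive_loss" %in% loss$flags)
  sel6 <- select_model(gibbs, list(loss), segs)
  expect_equal(sel6$source, "gibbs")
})

test_that("selection falls back to the grid when the MCMC has not converged", {
  g <- small_genome(50)
  segs <- exact_segments(0.55, g)
  gibbs <- sgzr:::new_cn_model(0.55, compute_ploidy(g$n_bins, g$C),
                               g$C, g$M, segs, source = "gibbs",
                               flags = "non_converged")
  alt <- sgzr:::new_cn_model(0.54, compute_ploidy(g$n_bins, g$C),
                             g$C, g$M, segs, source = "grid")
  sel <- select_model(gibbs, list(alt), segs)
  expect_equal(sel$source, "grid")
})

test_that("the high-purity screen reacts to LOH displacement of het SNPs", {
  no_var <- tibble::tibble(segment = integer(), origin = character(),
                           V = integer(), ccf = double())
  g <- tibble::tribble(
    ~chrom, ~n_bins, ~C, ~M,
    "chr1", 60L, 2L, 0L,
    "chr2", 60L, 2L, 0L,
    "chr3", 60L, 2L, 1L
  )
  # near-pure: LOH het SNPs displaced to minor fractions near 0
  hi <- simulate_specimen(sim_config(0.97, genome = g, variants = no_var,
                                     seed = 61))
  expect_true(high_purity_check(hi$snps))
  # fully pure with genome-wide LOH: het SNPs vanish from the het window
  g_loh <- tibble::tibble(chrom = paste0("chr", 1:3), n_bins = 60L,
                          C = 2L, M = 0L)
  pure <- simulate_specimen(sim_config(1, genome = g_loh, variants = no_var,
                                       seed = 63))
  expect_true(high_purity_check(pure$snps))
  # moderate purity: neither criterion fires
  lo <- simulate_specimen(sim_config(0.3, genome = g, variants = no_var,
                                     seed = 62))
  expect_false(high_purity_check(lo$snps))
  expect_false(high_purity_check(NULL))
  expect_false(high_purity_check(lo$snps[0, ]))
})
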