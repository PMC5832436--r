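#' Assemble a pipeline run configuration
#'
#' All tunable parameters of the pipeline stages in one named list that
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Master seed for simulation, segmentation permutations and
#'   MCMC.
#' @param ... Overrides of the defaults (see the returned list's names).
#' @return An object of class `sgz_run_config`.
#' @export
sgz_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # preprocess
    min_snp_depth = 20, het_lo = 0.10, het_hi = 0.90,
    gc_span = 0.3,
    # segmentation
    cbs_alpha = 0.01, n_perm = 1000L, min_bins = 10L,
    sd_floor_lr = 0.05, sd_floor_maf = 0.02,
    # copy-number model
    c_max = 10L, lambda = 1, loss_threshold = 0.10, use_mcmc = TRUE,
    # calling
    alpha = 0.01, purity_cap = 0.95, zygosity_min_purity = 0.20,
    subclonal_min_purity = 0.20, misfit_sd = 3, basic_delta = 0.10,
    # cohort
    e_G = 0.05, e_S = 0.10
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sgz_run_config")
}

#' @rdname sgz_run_config
#' @param config Configuration to serialize.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname sgz_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sgz_run_config, y[setdiff(names(y), "seed")] |>
            c(list(seed = y$seed)))
}

#' Run the full SGZ pipeline on one specimen
#'
#' Executes preprocess, segmentation, copy-number fit, and variant
#' classification in order, writing every intermediate (log-ratio TSV,
#' SEG-like segment table, model YAML/TSV, calls TSV + annotated VCF, and
#' a run log) so each stage can be inspected independently.
#'
#' @param specimen An `sgz_specimen` (from [simulate_specimen()] or
#'   [read_specimen()]).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param config [sgz_run_config()].
#' @return List with `profile`, `maf`, `segments`, `model`, `calls`,
#'   `basic_calls`, invisibly writable artifacts under `out_dir`.
#' @export
run_sgz_pipeline <- function(specimen, out_dir = NULL,
                             config = sgz_run_config()) {
  stopifnot(inherits(specimen, "sgz_specimen"))
  profile <- compute_log_ratio(specimen$bins) |>
    gc_correct(span = config$gc_span)
  maf <- select_het_snps(specimen$snps, min_depth = config$min_snp_depth,
                         het_lo = config$het_lo, het_hi = config$het_hi)
  bounds <- cbs_segment(profile, cbs_alpha = config$cbs_alpha,
                        n_perm = config$n_perm, min_bins = config$min_bins,
                        seed = config$seed)
  segments <- summarize_segments(bounds, profile, maf,
                                 sd_floor_lr = config$sd_floor_lr,
                                 sd_floor_maf = config$sd_floor_maf)
  model <- fit_copy_number(segments, snps = specimen$snps,
                           use_mcmc = config$use_mcmc,
                           seed = config$seed, c_max = config$c_max,
                           loss_threshold = config$loss_threshold,
                           lambda = config$lambda)
  calls <- classify_variants(
    specimen$variants, model, alpha = config$alpha,
    purity_cap = config$purity_cap,
    zygosity_min_purity = config$zygosity_min_purity,
    subclonal_min_purity = config$subclonal_min_purity,
    misfit_sd = config$misfit_sd
  )
  basic <- specimen$variants
  basic$status <- basic_method_classify(basic$af, delta = config$basic_delta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(profile, file.path(out_dir, "log_ratio.tsv"))
    readr::write_tsv(maf, file.path(out_dir, "maf.tsv"))
    write_segments(segments, file.path(out_dir, "segments.tsv"))
    write_cn_model(model, file.path(out_dir, "model"))
    write_calls(calls, file.path(out_dir, "calls"))
    readr::write_tsv(basic, file.path(out_dir, "basic_calls.tsv"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
    log <- c(
      sprintf("sgzr %s", as.character(utils::packageVersion("sgzr"))),
      sprintf("seed: %d", config$seed),
      sprintf("model source: %s", model$source),
      sprintf("purity: %.3f ploidy: %.3f", model$purity, model$ploidy),
      sprintf("flags: %s", paste(model$flags, collapse = ",")),
      if (!is.null(model$selection$audit)) {
        audit <- model$selection$audit
        sprintf("selection rule %s candidate %d: %s", audit$rule,
                audit$candidate, ifelse(audit$passed, "pass", "fail"))
      }
    )
    writeLines(log, file.path(out_dir, "run.log"))
  }
  list(profile = profile, maf = maf, segments = segments, model = model,
       calls = calls, basic_calls = basic)
}

#' Score calls against a simulated specimen's truth
#'
#' Joins calls to the truth table by position and computes the call rate
#' (non-ambiguous fraction), somatic accuracy (fraction of called
#' true-somatic variants called somatic or subclonal somatic) and germline
#' accuracy (fraction of called true-germline variants called germline).
#' Accuracies are `NA` when no variant of that class was called.
#'
#' @param calls `sgz_calls` tibble (or any tibble with `chrom`, `pos`,
#'   `status`).
#' @param truth Truth variant table (`chrom`, `pos`, `origin`).
#' @return One-row tibble: `n`, `n_called`, `call_rate`,
#'   `somatic_accuracy`, `germline_accuracy`.
#' @export
evaluate_against_truth <- function(calls, truth) {
  stopifnot(all(c("chrom", "pos", "status") %in% names(calls)),
            all(c("chrom", "pos", "origin") %in% names(truth)))
  keys <- intersect(c("chrom", "pos", "ref", "alt"), names(calls))
  keys <- intersect(keys, names(truth))
  j <- dplyr::inner_join(calls, truth[, c(keys, "origin")], by = keys)
  if (nrow(j) != nrow(calls)) {
    stop("truth table does not cover all calls (key mismatch)")
  }
  called <- j$status != "ambiguous"
  som <- j$origin == "somatic" & called
  ger <- j$origin == "germline" & called
  tibble::tibble(
    n = nrow(j),
    n_called = sum(called),
    call_rate = mean(called),
    somatic_accuracy = if (any(som)) {
      mean(j$status[som] %in% c("somatic", "subclonal_somatic"))
    } else NA_real_,
    germline_accuracy = if (any(ger)) {
      mean(j$status[ger] == "germline")
    } else NA_real_
  )
}
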