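# Readers and writers for the pipeline's plain-text interchange formats.
# Coordinates are BED-style 0-based half-open in TSVs; the VCF is 1-based.

#' Write a simulated specimen to a directory
#'
#' Writes `coverage.tsv` (chrom, start, end, gc, tumor_depth,
#' normal_depth), `snps.tsv` (chrom, pos, depth, alt_depth), `variants.vcf`
#' (minimal VCF 4.2 with DP/AD/AF in INFO) and, when truth is present,
#' `truth_segments.tsv` and `truth_variants.tsv` plus `truth.yaml` (purity,
#' ploidy).
#'
#' @param specimen An `sgz_specimen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_specimen <- function(specimen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(specimen$bins, file.path(dir, "coverage.tsv"))
  readr::write_tsv(specimen$snps, file.path(dir, "snps.tsv"))
  write_variants_vcf(specimen$variants, file.path(dir, "variants.vcf"))
  if (!is.null(specimen$truth)) {
    readr::write_tsv(specimen$truth$segments,
                     file.path(dir, "truth_segments.tsv"))
    if (!is.null(specimen$truth$variants)) {
      readr::write_tsv(specimen$truth$variants,
                       file.path(dir, "truth_variants.tsv"))
    }
    yaml::write_yaml(list(purity = specimen$truth$purity,
                          ploidy = specimen$truth$ploidy),
                     file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' Read specimen inputs from a directory
#'
#' Counterpart of [write_specimen()]; truth files are optional.
#'
#' @param dir Directory holding `coverage.tsv`, `snps.tsv`, `variants.vcf`.
#' @return An `sgz_specimen` (truth `NULL` when absent).
#' @export
read_specimen <- function(dir) {
  bins <- readr::read_tsv(file.path(dir, "coverage.tsv"),
                          show_col_types = FALSE)
  snps <- readr::read_tsv(file.path(dir, "snps.tsv"), show_col_types = FALSE)
  variants <- read_variants_vcf(file.path(dir, "variants.vcf"))
  truth <- NULL
  if (file.exists(file.path(dir, "truth.yaml"))) {
    y <- yaml::read_yaml(file.path(dir, "truth.yaml"))
    truth <- list(
      purity = y$purity, ploidy = y$ploidy,
      segments = readr::read_tsv(file.path(dir, "truth_segments.tsv"),
                                 show_col_types = FALSE),
      variants = if (file.exists(file.path(dir, "truth_variants.tsv"))) {
        readr::read_tsv(file.path(dir, "truth_variants.tsv"),
                        show_col_types = FALSE)
      }
    )
  }
  structure(list(bins = bins, snps = snps, variants = variants,
                 truth = truth, config = NULL),
            class = "sgz_specimen")
}

# minimal single-sample VCF with DP/AD/AF INFO keys (text, uncompressed)
write_variants_vcf <- function(variants, path, extra_info = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt read depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt allele frequency\">"
  )
  if (!is.null(extra_info)) header <- c(header, extra_info)
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ad <- if ("alt_depth" %in% names(variants)) {
    variants$alt_depth
  } else {
    as.integer(round(variants$depth * variants$af))
  }
  info <- sprintf("DP=%d;AD=%d;AF=%.6g", variants$depth, ad, variants$af)
  if ("info_extra" %in% names(variants)) {
    info <- paste0(info, ";", variants$info_extra)
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos + 1L, variants$ref,
                  variants$alt, info)
  writeLines(c(header, if (nrow(variants)) body), path)
  invisible(path)
}

#' Read candidate variants from a VCF
#'
#' Uses `vcfR` when available, falling back to a minimal tab parser for
#' the single-sample VCFs written by this package. Requires DP and either
#' AD or AF in INFO. Positions are converted to the package's internal
#' 0-based convention.
#'
#' @param path VCF file path.
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `depth`, `alt_depth`, `af`.
#' @export
read_variants_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- fix$INFO %||% character()
    if (nrow(fix) == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            depth = integer(), alt_depth = integer(),
                            af = double()))
    }
    get_info <- function(key) {
      m <- stringr::str_match(vcfR::getINFO(v), paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
      as.numeric(m)
    }
    dp <- get_info("DP"); ad <- get_info("AD"); af <- get_info("AF")
    if (all(is.na(af)) && !all(is.na(ad))) af <- ad / dp
    if (all(is.na(ad)) && !all(is.na(af))) ad <- round(af * dp)
    return(tibble::tibble(
      chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L, ref = fix$REF,
      alt = fix$ALT, depth = as.integer(dp), alt_depth = as.integer(ad),
      af = af
    ))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          depth = integer(), alt_depth = integer(),
                          af = double()))
  }
  f <- do.call(rbind, strsplit(lines, "\t"))
  grab <- function(info, key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    as.numeric(m)
  }
  dp <- grab(f[, 8], "DP"); ad <- grab(f[, 8], "AD"); af <- grab(f[, 8], "AF")
  if (all(is.na(af))) af <- ad / dp
  if (all(is.na(ad))) ad <- round(af * dp)
  tibble::tibble(chrom = f[, 1], pos = as.integer(f[, 2]) - 1L,
                 ref = f[, 4], alt = f[, 5], depth = as.integer(dp),
                 alt_depth = as.integer(ad), af = af)
}

#' Write segments as a SEG-like TSV
#' @param segments Segment summary table.
#' @param path Output file.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(segments, path)
  invisible(path)
}

#' Write a fitted copy-number model as a YAML header and segment TSV
#'
#' `model.yaml` holds purity, ploidy, normalization ploidy, MSEs, source
#' and flags; `model_segments.tsv` the per-segment C, M and expectations.
#'
#' @param model `sgz_cn_model`.
#' @param dir Output directory.
#' @export
write_cn_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    list(purity = model$purity, ploidy = model$ploidy, psi0 = model$psi0,
         mse_lr = model$mse_lr, mse_maf = model$mse_maf,
         source = model$source, flags = as.list(model$flags)),
    file.path(dir, "model.yaml")
  )
  readr::write_tsv(model$segments, file.path(dir, "model_segments.tsv"))
  invisible(dir)
}

#' Read a copy-number model written by [write_cn_model()]
#' @param dir Model directory.
#' @return `sgz_cn_model`.
#' @export
read_cn_model <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "model.yaml"))
  seg <- readr::read_tsv(file.path(dir, "model_segments.tsv"),
                         show_col_types = FALSE)
  structure(
    list(purity = y$purity, ploidy = y$ploidy, psi0 = y$psi0,
         segments = seg, mse_lr = y$mse_lr, mse_maf = y$mse_maf,
         source = y$source, flags = unlist(y$flags) %||% character()),
    class = "sgz_cn_model"
  )
}

#' Write calls as TSV and annotated VCF
#'
#' The VCF mirror carries INFO keys SGZ_STATUS, SGZ_ZYG, SGZ_PG, SGZ_PS,
#' SGZ_AFG, SGZ_AFS, SGZ_REASON.
#'
#' @param calls `sgz_calls` tibble.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.vcf`.
#' @export
write_calls <- function(calls, prefix) {
  readr::write_tsv(calls, paste0(prefix, ".tsv"))
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  v <- calls
  v$alt_depth <- as.integer(round(v$depth * v$af))
  v$info_extra <- sprintf(
    "SGZ_STATUS=%s;SGZ_ZYG=%s;SGZ_PG=%s;SGZ_PS=%s;SGZ_AFG=%s;SGZ_AFS=%s;SGZ_REASON=%s",
    fmt(v$status), fmt(v$zygosity), fmt(signif(v$p_germline, 4)),
    fmt(signif(v$p_somatic, 4)), fmt(signif(v$af_germline, 4)),
    fmt(signif(v$af_somatic, 4)), fmt(v$reason)
  )
  extra <- c(
    "##INFO=<ID=SGZ_STATUS,Number=1,Type=String,Description=\"SGZ somatic/germline status\">",
    "##INFO=<ID=SGZ_ZYG,Number=1,Type=String,Description=\"SGZ tumor zygosity\">",
    "##INFO=<ID=SGZ_PG,Number=1,Type=Float,Description=\"Two-tailed binomial p-value, germline hypothesis\">",
    "##INFO=<ID=SGZ_PS,Number=1,Type=Float,Description=\"Two-tailed binomial p-value, somatic hypothesis\">",
    "##INFO=<ID=SGZ_AFG,Number=1,Type=Float,Description=\"Expected germline allele frequency\">",
    "##INFO=<ID=SGZ_AFS,Number=1,Type=Float,Description=\"Expected somatic allele frequency\">",
    "##INFO=<ID=SGZ_REASON,Number=1,Type=String,Description=\"No-call reason\">"
  )
  write_variants_vcf(v, paste0(prefix, ".vcf"), extra_info = extra)
  invisible(prefix)
}
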