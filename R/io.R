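# Variant-table parsing, family-count input and the end-to-end pipeline.

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

# parse "p.V33A", "V33A" or "p.Val33Ala" into (ref_aa, position, alt_aa)
.parse_variant_string <- function(x) {
  x <- sub("^p\\.", "", trimws(x))
  m3 <- regmatches(x, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", x))[[1]]
  if (length(m3) == 4 && all(c(m3[2], m3[4]) %in% names(.aa3to1))) {
    return(list(ref_aa = unname(.aa3to1[m3[2]]),
                position = as.integer(m3[3]),
                alt_aa = unname(.aa3to1[m3[4]])))
  }
  m1 <- regmatches(x, regexec("^([A-Za-z])(\\d+)([A-Za-z])$", x))[[1]]
  if (length(m1) == 4) {
    ref <- toupper(m1[2])
    alt <- toupper(m1[4])
    if (all(c(ref, alt) %in% AA_ALPHABET)) {
      return(list(ref_aa = ref, position = as.integer(m1[3]), alt_aa = alt))
    }
  }
  NULL
}

PHENOTYPE_LEVELS <- c("MODY", "PHHI", "PNDM", "normoglycemic", "unknown")

#' Parse a variant table from TSV
#'
#' Reads a tab-delimited variant table (UTF-8, `#` comment lines). Protein
#' changes are accepted either as a `variant` column (`V33A`, `p.V33A` or
#' `p.Val33Ala`) or as `ref_aa` / `position` / `alt_aa` columns; when both
#' notations are present they are cross-validated. Typographic minus signs
#' (U+2212) in numeric columns are normalized to ASCII. Missing predictor
#' scores stay missing; nothing is imputed.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `variant`, `position`, `ref_aa`, `alt_aa`,
#'   `phenotype` and any further columns (predictor scores, `families`,
#'   kinetic annotations) as read.
#' @export
parse_variant_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  # normalize typographic minus in character columns, then re-type
  raw <- dplyr::mutate(raw, dplyr::across(
    dplyr::where(is.character), ~ gsub("−", "-", .x)))
  raw <- readr::type_convert(raw, col_types = readr::cols())

  has_var <- "variant" %in% names(raw)
  has_triplet <- all(c("ref_aa", "position", "alt_aa") %in% names(raw))
  if (!has_var && !has_triplet) {
    abort("need a `variant` column or `ref_aa`/`position`/`alt_aa` columns")
  }
  if (has_var) {
    parsed <- lapply(raw$variant, .parse_variant_string)
    bad <- which(vapply(parsed, is.null, logical(1)))
    if (length(bad) > 0) {
      abort(sprintf("line %d: cannot parse variant %s",
                    bad[1] + 1, dQuote(raw$variant[bad[1]], FALSE)))
    }
    p <- dplyr::bind_rows(parsed)
    if (has_triplet) {
      mism <- which(p$ref_aa != raw$ref_aa | p$position != raw$position |
                    p$alt_aa != raw$alt_aa)
      if (length(mism) > 0) {
        abort(sprintf("line %d: variant notation disagrees with ref/pos/alt columns",
                      mism[1] + 1))
      }
    }
    raw$ref_aa <- p$ref_aa
    raw$position <- p$position
    raw$alt_aa <- p$alt_aa
  }
  same <- which(raw$ref_aa == raw$alt_aa)
  if (length(same) > 0) {
    abort(sprintf("line %d: reference and alternate residue are identical",
                  same[1] + 1))
  }
  key <- paste0(raw$ref_aa, raw$position, raw$alt_aa)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("line %d: duplicate variant row %s", dup[1] + 1,
                  dQuote(key[dup[1]], FALSE)))
  }
  if ("phenotype" %in% names(raw)) {
    badph <- setdiff(unique(raw$phenotype[!is.na(raw$phenotype)]),
                     PHENOTYPE_LEVELS)
    if (length(badph) > 0) {
      abort(sprintf("unknown phenotype label(s): %s",
                    paste(dQuote(badph, FALSE), collapse = ", ")))
    }
  }
  raw$variant <- key
  dplyr::relocate(raw, "variant", "position", "ref_aa", "alt_aa")
}

#' Write a variant table to TSV
#'
#' @param x Variant tibble.
#' @param path Output path.
#' @param comment Optional character vector written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path, comment = NULL) {
  header <- if (!is.null(comment)) paste0("# ", comment) else character(0)
  body <- readr::format_tsv(x)
  writeLines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read per-residue family counts from TSV
#'
#' @param path TSV with columns `position`, `families`.
#' @return Tibble with integer `position` and `families`.
#' @export
read_family_counts <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("position", "families") %in% names(out)))
  if (any(out$families < 0, na.rm = TRUE)) {
    abort("family counts must be non-negative")
  }
  out
}

#' Pipeline configuration
#'
#' @param variants Path to a variant TSV (optional).
#' @param alignment Path to an aligned FASTA (optional).
#' @param family_counts Path to a family-count TSV (optional).
#' @param out_dir Output directory (created if absent).
#' @param neutral_label Neutral phenotype label for calibration.
#' @param gv_threshold Conservation cutoff, Grantham units.
#' @param k Spread multiplier for calibration.
#' @param ci Whether to bootstrap CIs during calibration.
#' @param seed Integer seed for stochastic steps.
#' @param beta_cell [beta_cell_config()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(variants = NULL, alignment = NULL,
                            family_counts = NULL, out_dir = tempdir(),
                            neutral_label = "normoglycemic",
                            gv_threshold = 61.3, k = 2, ci = FALSE,
                            seed = 1L, beta_cell = beta_cell_config()) {
  for (p in c(variants, alignment, family_counts)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input path does not exist: %s", p))
    }
  }
  structure(list(variants = variants, alignment = alignment,
                 family_counts = family_counts, out_dir = out_dir,
                 neutral_label = neutral_label, gv_threshold = gv_threshold,
                 k = k, ci = ci, seed = as.integer(seed),
                 beta_cell = beta_cell),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()] (the `beta_cell` block maps to
#'   [beta_cell_config()] arguments).
#' @return List of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  bc <- do.call(beta_cell_config, y$beta_cell %||% list())
  y$beta_cell <- NULL
  do.call(pipeline_config, c(y, list(beta_cell = bc)))
}

#' Run the analysis pipeline
#'
#' Executes the feasible stages in analysis order -- threshold calibration
#' and predictor evaluation (when a variant table is configured), then
#' conservation profiling and the GV/frequency correlation (when an
#' alignment is configured) -- and writes their TSV outputs plus a JSON-like
#' manifest (input hashes, settings, package version) to the output
#' directory. Re-running the same configuration reproduces identical
#' outputs; stages without inputs are skipped with a message.
#'
#' @param config [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a list with the computed objects (`thresholds`,
#'   `metrics`, `profile`, `correlation`, as available) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  inputs <- purrr::compact(config[c("variants", "alignment", "family_counts")])
  manifest <- list(
    package_version = as.character(utils::packageVersion("glucovar")),
    seed = config$seed,
    settings = list(neutral_label = config$neutral_label,
                    gv_threshold = config$gv_threshold, k = config$k),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )

  if (!is.null(config$variants)) {
    variants <- parse_variant_table(config$variants)
    thresholds <- calibrate_thresholds(
      variants, neutral_label = config$neutral_label, k = config$k,
      ci = config$ci, seed = config$seed)
    write_variant_table(thresholds, file.path(config$out_dir, "thresholds.tsv"))
    metrics <- purrr::map(thresholds$predictor, function(pred) {
      thr <- thresholds[thresholds$predictor == pred, ]
      calls <- apply_threshold(variants[[pred]], thr)
      calls[is.na(variants[[pred]])] <- NA
      class_metrics(variants$phenotype, calls == "deleterious", "phenotype")
    })
    names(metrics) <- thresholds$predictor
    metrics_tbl <- purrr::imap(metrics, function(m, pred) {
      dplyr::mutate(tidy(m), predictor = pred,
                    false_positive_ratio = m$false_positive_ratio)
    }) |> dplyr::bind_rows()
    write_variant_table(metrics_tbl,
                        file.path(config$out_dir, "class_metrics.tsv"))
    results$variants <- variants
    results$thresholds <- thresholds
    results$metrics <- metrics
  } else {
    inform("no variant table configured; calibration/evaluation skipped")
  }

  if (!is.null(config$alignment)) {
    aln <- read_alignment(config$alignment)
    profile <- conservation_profile(map_alignment(aln),
                                    gv_threshold = config$gv_threshold)
    write_profile(profile, file.path(config$out_dir, "conservation.tsv"))
    results$profile <- profile
    if (!is.null(config$family_counts)) {
      fam <- read_family_counts(config$family_counts)
      results$correlation <- conservation_frequency_corr(profile, fam)
      write_variant_table(results$correlation,
                          file.path(config$out_dir, "gv_frequency_corr.tsv"))
    }
  } else {
    inform("no alignment configured; conservation stage skipped")
  }

  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}
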