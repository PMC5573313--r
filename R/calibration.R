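# Evidence-based threshold calibration from neutral (normoglycemic) variant
# score distributions: center +/- k * spread in the deleterious direction.

#' Default predictor conventions
#'
#' Conventions for the nine supported variant-effect predictors: which
#' direction of the score indicates a deleterious call, whether the output
#' is continuous or binary, and which center statistic the evidence-based
#' calibration uses (median by default; mean for SNAP2).
#'
#' @return Tibble with columns `predictor`, `orientation`
#'   (`"lower_is_deleterious"` / `"higher_is_deleterious"` / `NA` for
#'   binary), `output_type`, `center_stat`, `default_threshold`.
#' @export
predictor_specs <- function() {
  tibble::tribble(
    ~predictor,      ~orientation,            ~output_type, ~center_stat, ~default_threshold,
    "sift",          "lower_is_deleterious",  "continuous", "median",     0.05,
    "polyphen2",     "higher_is_deleterious", "continuous", "median",     0.5,
    "phd_snp",       NA,                      "binary",     NA,           NA,
    "popmusic_ddg",  "higher_is_deleterious", "continuous", "median",     0,
    "snap2",         "higher_is_deleterious", "continuous", "mean",       0,
    "snpsgo",        NA,                      "binary",     NA,           NA,
    "snpsgo_go",     NA,                      "binary",     NA,           NA,
    "imutant3",      "lower_is_deleterious",  "continuous", "median",     0,
    "agvgd_gd",      "higher_is_deleterious", "continuous", "median",     61.3,
    "evmutation",    "lower_is_deleterious",  "continuous", "median",     0
  )
}

#' Evidence-based decision threshold from neutral scores
#'
#' Places the decision boundary for a continuous predictor at the center of
#' the neutral-variant score distribution shifted by `k` spreads in the
#' deleterious direction: `center - k * spread` when lower scores are
#' deleterious, `center + k * spread` when higher scores are.
#'
#' @param neutral_scores Numeric scores of neutral (normoglycemic) variants;
#'   at least 3 finite values.
#' @param orientation `"lower_is_deleterious"` or `"higher_is_deleterious"`.
#' @param k Spread multiplier (default 2).
#' @param center_stat `"median"` (default) or `"mean"`.
#' @param spread_stat `"sd"` (sample standard deviation, default) or
#'   `"mad"` (1.4826-scaled median absolute deviation).
#' @param predictor Optional predictor name carried into the result.
#' @return One-row tibble of class data: `predictor`, `n`, `center`,
#'   `spread`, `k`, `threshold`, `direction` (`"below"`/`"above"`: the side
#'   on which a score is called deleterious), `center_stat`, `spread_stat`.
#' @export
#' @examples
#' evidence_threshold(c(-1, -2, -3, -4, -5), "lower_is_deleterious")
evidence_threshold <- function(neutral_scores, orientation, k = 2,
                               center_stat = c("median", "mean"),
                               spread_stat = c("sd", "mad"),
                               predictor = NA_character_) {
  center_stat <- arg_match(center_stat)
  spread_stat <- arg_match(spread_stat)
  orientation <- arg_match(orientation,
                           c("lower_is_deleterious", "higher_is_deleterious"))
  if (anyNA(neutral_scores) || any(!is.finite(neutral_scores))) {
    abort("neutral scores must be finite and non-missing")
  }
  if (length(neutral_scores) < 3) abort("need at least 3 neutral scores")
  center <- if (center_stat == "median") median(neutral_scores)
            else mean(neutral_scores)
  spread <- if (spread_stat == "sd") sd(neutral_scores)
            else mad(neutral_scores)
  sign <- if (orientation == "lower_is_deleterious") -1 else 1
  tibble::tibble(
    predictor = predictor,
    n = length(neutral_scores),
    center = center,
    spread = spread,
    k = k,
    threshold = center + sign * k * spread,
    direction = if (sign < 0) "below" else "above",
    center_stat = center_stat,
    spread_stat = spread_stat
  )
}

#' Bootstrap confidence interval for the center statistic
#'
#' Nonparametric percentile bootstrap CI of the median (or mean) of a score
#' sample. Constant data yield a zero-width interval with a warning.
#'
#' @param scores Numeric vector, at least 5 finite values.
#' @param center_stat `"median"` (default) or `"mean"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return One-row tibble: `center`, `ci_low`, `ci_high`, `level`, `n_boot`.
#' @export
center_ci <- function(scores, center_stat = c("median", "mean"),
                      level = 0.95, n_boot = 10000, seed = NULL) {
  center_stat <- arg_match(center_stat)
  scores <- scores[is.finite(scores)]
  if (length(scores) < 5) abort("need at least 5 finite scores")
  stat <- if (center_stat == "median") median else mean
  if (sd(scores) == 0) {
    warn("constant scores: zero-width confidence interval")
    return(tibble::tibble(center = scores[1], ci_low = scores[1],
                          ci_high = scores[1], level = level, n_boot = n_boot))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    stat(sample(scores, length(scores), replace = TRUE))
  }, numeric(1))
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  tibble::tibble(center = stat(scores), ci_low = qs[1], ci_high = qs[2],
                 level = level, n_boot = n_boot)
}

#' Calibrate evidence-based thresholds for every continuous predictor
#'
#' Data-frame-first wrapper: extracts the neutral-class scores of each
#' continuous predictor from a variant table and calibrates its threshold
#' with [evidence_threshold()], optionally with a bootstrap CI of the center.
#'
#' @param variants Variant tibble with a `phenotype` column and one score
#'   column per predictor (missing scores as `NA`).
#' @param specs Predictor conventions, see [predictor_specs()]. Predictors
#'   without a matching column are skipped.
#' @param neutral_label Phenotype label of the neutral class (default
#'   `"normoglycemic"`).
#' @param k Spread multiplier.
#' @param ci Compute bootstrap CIs of the centers (slower).
#' @param n_boot,seed Passed to [center_ci()].
#' @return Tibble with one row per calibrated predictor: the
#'   [evidence_threshold()] columns plus `ci_low`, `ci_high` (`NA` when
#'   `ci = FALSE`).
#' @export
calibrate_thresholds <- function(variants, specs = predictor_specs(),
                                 neutral_label = "normoglycemic", k = 2,
                                 ci = FALSE, n_boot = 10000, seed = NULL) {
  stopifnot(is.data.frame(variants), "phenotype" %in% names(variants))
  neutral <- dplyr::filter(variants, .data$phenotype == neutral_label)
  if (nrow(neutral) == 0) abort("no variants carry the neutral label")
  cont <- dplyr::filter(specs, .data$output_type == "continuous",
                        .data$predictor %in% names(variants))
  rows <- purrr::pmap(
    list(cont$predictor, cont$orientation, cont$center_stat),
    function(pred, orient, cstat) {
      scores <- neutral[[pred]]
      scores <- scores[is.finite(scores)]
      if (length(scores) < 3) return(NULL)
      thr <- evidence_threshold(scores, orient, k = k, center_stat = cstat,
                                predictor = pred)
      if (ci && length(scores) >= 5) {
        ci_tbl <- center_ci(scores, cstat, n_boot = n_boot, seed = seed)
        thr$ci_low <- ci_tbl$ci_low
        thr$ci_high <- ci_tbl$ci_high
      } else {
        thr$ci_low <- NA_real_
        thr$ci_high <- NA_real_
      }
      thr
    }
  )
  dplyr::bind_rows(purrr::compact(rows))
}

#' Apply a calibrated threshold to scores
#'
#' Calls a score deleterious when it lies strictly past the threshold in the
#' deleterious direction; scores exactly at the threshold, and missing
#' scores, are not called.
#'
#' @param scores Numeric vector (NA allowed).
#' @param threshold One-row tibble from [evidence_threshold()] (or a list
#'   with `threshold` and `direction`).
#' @return Factor with levels `deleterious`, `not_called`; `NA` scores map
#'   to `not_called`.
#' @export
apply_threshold <- function(scores, threshold) {
  thr <- threshold$threshold
  dir <- threshold$direction
  stopifnot(length(thr) == 1, dir %in% c("below", "above"))
  hit <- if (dir == "below") scores < thr else scores > thr
  hit[is.na(hit)] <- FALSE
  factor(ifelse(hit, "deleterious", "not_called"),
         levels = c("deleterious", "not_called"))
}

#' Percentage of a class passing a threshold
#'
#' Fraction (as an integer percent) of variants of one phenotype class that
#' are called deleterious, among class members with a score.
#'
#' @param calls Factor/character vector of calls (`"deleterious"` /
#'   `"not_called"`), `NA` for missing scores.
#' @param labels Phenotype labels parallel to `calls`.
#' @param target_label Class to evaluate.
#' @return Integer percent (0-100).
#' @export
pass_rate <- function(calls, labels, target_label) {
  stopifnot(length(calls) == length(labels))
  in_class <- labels == target_label & !is.na(labels)
  scored <- in_class & !is.na(calls)
  if (!any(scored)) abort("no scored variants in the target class")
  round(100 * sum(calls[scored] == "deleterious") / sum(scored))
}
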