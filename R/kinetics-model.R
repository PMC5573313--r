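# Beta-cell model: enzyme activity, relative activity index (RAI) and the
# threshold for glucose-stimulated insulin release (GSIR-T).

#' Beta-cell model configuration
#'
#' Constants of the heterozygous beta-cell model used to derive RAI and
#' GSIR-T from fitted kinetic parameters. Defaults place the wild-type
#' glucose setpoint at 5.0 mM, evaluate activity at 2.5 mM ATP, censor
#' GSIR-T at 7.1 mM and RAI below 0.01, and assume a 50:50 allele dose with
#' no compensatory upregulation of the wild-type allele.
#'
#' @param g_ref Reference glucose setpoint (mM) at which the wild-type
#'   phosphorylation rate defines the insulin-release threshold condition.
#' @param atp_conc ATP concentration (mM) at which activity is evaluated.
#' @param gsirt_cap Censoring cap for GSIR-T (mM glucose); computed
#'   thresholds at or above it are reported as "greater or equal".
#' @param rai_floor Censoring floor for RAI; values below it are reported as
#'   "less than".
#' @param het_fraction Allele dose of each allele in the heterozygote.
#' @param compensation Multiplier on the wild-type allele's activity
#'   (compensatory upregulation; 1 = none).
#' @param tol Solver tolerance for the GSIR-T root (mM glucose).
#' @return A list of class `beta_cell_config`.
#' @export
beta_cell_config <- function(g_ref = 5.0, atp_conc = 2.5, gsirt_cap = 7.1,
                             rai_floor = 0.01, het_fraction = 0.5,
                             compensation = 1.0, tol = 1e-6) {
  stopifnot(g_ref > 0, atp_conc > 0, gsirt_cap > g_ref,
            rai_floor >= 0, het_fraction > 0, het_fraction <= 1,
            compensation >= 0, tol > 0)
  structure(
    list(g_ref = g_ref, atp_conc = atp_conc, gsirt_cap = gsirt_cap,
         rai_floor = rai_floor, het_fraction = het_fraction,
         compensation = compensation, tol = tol),
    class = "beta_cell_config"
  )
}

#' Kinetic parameter set for one enzyme form
#'
#' Bundles the fitted glucose-dependence (Hill) and ATP-dependence
#' (Michaelis) constants of one glucokinase form for use in [activity()],
#' [compute_rai()] and [gsir_threshold()].
#'
#' @param s05 Glucose concentration at half-maximal activity (mM).
#' @param n_h Hill coefficient (dimensionless, cooperativity).
#' @param kcat Turnover number (1/s).
#' @param km_atp Michaelis constant for ATP (mM); 0 drops the ATP factor.
#' @param no_activity Censor flag: no measurable activity; activity is 0 and
#'   derived RAI is censored at the floor.
#' @return A list of class `kinetic_params`.
#' @export
#' @examples
#' wt <- kinetic_params(s05 = 8.82, n_h = 1.72, kcat = 43.8, km_atp = 0.36)
kinetic_params <- function(s05, n_h, kcat, km_atp = 0, no_activity = FALSE) {
  if (!no_activity) {
    stopifnot(is.finite(s05), s05 > 0, is.finite(n_h), n_h > 0.5, n_h < 4,
              is.finite(kcat), kcat >= 0, is.finite(km_atp), km_atp >= 0)
  }
  structure(list(s05 = s05, n_h = n_h, kcat = kcat, km_atp = km_atp,
                 no_activity = isTRUE(no_activity)),
            class = "kinetic_params")
}

.as_params <- function(p) {
  if (inherits(p, "kinetic_params")) return(p)
  if (is.list(p) || is.data.frame(p)) {
    p <- as.list(p)
    if (isTRUE(p$no_activity %||% FALSE)) {
      return(kinetic_params(NA, NA, NA, NA, no_activity = TRUE))
    }
    return(kinetic_params(p$s05, p$n_h, p$kcat, p$km_atp %||% 0))
  }
  abort("expected a kinetic_params object or a list/one-row data frame")
}

#' Glucose-phosphorylation rate of one enzyme form
#'
#' Evaluates the cooperative (Hill) glucose dependence times a Michaelis
#' factor for ATP:
#' \deqn{A(G) = k_{cat} \frac{G^{n_H}}{S_{0.5}^{n_H} + G^{n_H}}
#'       \cdot \frac{[ATP]}{[ATP] + K_{M,ATP}}}
#' Vectorised over `glucose`.
#'
#' @param params [kinetic_params()] (or coercible list / one-row data frame).
#' @param glucose Glucose concentration(s), mM (>= 0).
#' @param atp ATP concentration, mM (> 0).
#' @return Rate(s) in 1/s per enzyme; 0 everywhere for `no_activity` forms.
#' @export
activity <- function(params, glucose, atp) {
  params <- .as_params(params)
  stopifnot(all(glucose >= 0), atp > 0)
  if (params$no_activity) return(rep(0, length(glucose)))
  hill <- glucose^params$n_h / (params$s05^params$n_h + glucose^params$n_h)
  hill[glucose == 0] <- 0  # guard 0^0 when n_h edge cases arise
  params$kcat * hill * atp / (atp + params$km_atp)
}

#' Stability index of an enzyme preparation
#'
#' Percent activity retained after incubation relative to an unincubated
#' control.
#'
#' @param rate_incubated,rate_control Rates (1/s); `rate_control` > 0.
#' @return Percentage, `100 * rate_incubated / rate_control`.
#' @export
stability_index <- function(rate_incubated, rate_control) {
  if (any(rate_control <= 0)) abort("control rate must be positive")
  100 * rate_incubated / rate_control
}

#' Relative activity index (RAI) of a variant
#'
#' Ratio of the variant's to the wild type's phosphorylation rate at the
#' reference condition (`g_ref` mM glucose, `atp_conc` mM ATP). Wild type has
#' RAI 1 by construction; values below `rai_floor` are censored.
#'
#' @param var,wt [kinetic_params()] for the variant and wild type.
#' @param cfg [beta_cell_config()].
#' @return One-row tibble: `rai` (numeric; the floor value when censored),
#'   `rai_censored` (logical), `rai_label` (e.g. `"<0.01"` or `"0.51"`).
#' @export
compute_rai <- function(var, wt, cfg = beta_cell_config()) {
  var <- .as_params(var)
  wt <- .as_params(wt)
  if (wt$no_activity) abort("wild type must be fully parameterized")
  a_wt <- activity(wt, cfg$g_ref, cfg$atp_conc)
  rai <- activity(var, cfg$g_ref, cfg$atp_conc) / a_wt
  censored <- rai < cfg$rai_floor
  tibble::tibble(
    rai = rai,
    rai_censored = censored,
    rai_label = if (censored) sprintf("<%.2f", cfg$rai_floor)
                else sprintf("%.2f", rai)
  )
}

# Monotone-increasing root function for the GSIR-T condition:
# combined heterozygous activity at G equals the wild-type setpoint rate.
.gsirt_gap <- function(g, var, wt, cfg) {
  cfg$het_fraction * cfg$compensation * activity(wt, g, cfg$atp_conc) +
    cfg$het_fraction * activity(var, g, cfg$atp_conc) -
    activity(wt, cfg$g_ref, cfg$atp_conc)
}

#' Threshold for glucose-stimulated insulin release (GSIR-T)
#'
#' Finds the blood glucose concentration at which a heterozygous beta cell
#' (allele dose `het_fraction` of wild type plus `het_fraction` of the
#' variant, wild-type allele optionally upregulated by `compensation`)
#' reaches the wild-type reference phosphorylation rate at `g_ref`. The gap
#' function is monotone in glucose, so the root is located by bracket
#' expansion (upper bound doubling from 50 to at most 500 mM) followed by
#' bisection to `cfg$tol`. Wild type returns exactly `g_ref`. Computed
#' thresholds at or above `gsirt_cap` (including inactive variants and
#' failures to bracket) are censored at the cap.
#'
#' @param var,wt [kinetic_params()] for the variant and wild type.
#' @param cfg [beta_cell_config()].
#' @return One-row tibble: `gsirt_raw` (unrounded root, mM; `NA` when no
#'   root was bracketed), `gsirt` (rounded to 0.1 mM, capped when censored),
#'   `gsirt_censored` (logical), `gsirt_label` (e.g. `"5.9"` or `">=7.1"`).
#' @export
gsir_threshold <- function(var, wt, cfg = beta_cell_config()) {
  var <- .as_params(var)
  wt <- .as_params(wt)
  if (wt$no_activity) abort("wild type must be fully parameterized")
  f <- function(g) .gsirt_gap(g, var, wt, cfg)

  root <- NA_real_
  if (abs(f(cfg$g_ref)) <= 1e-12 * activity(wt, cfg$g_ref, cfg$atp_conc)) {
    root <- cfg$g_ref  # variant indistinguishable from wild type
  } else {
    lower <- 0.01
    upper <- 50
    while (f(upper) < 0 && upper < 500) upper <- min(2 * upper, 500)
    if (f(lower) <= 0 && f(upper) >= 0) {
      lo <- lower
      hi <- upper
      while (hi - lo > cfg$tol) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
      }
      root <- (lo + hi) / 2
    }
  }

  censored <- is.na(root) || root >= cfg$gsirt_cap
  reported <- if (censored) cfg$gsirt_cap else round(root, 1)
  tibble::tibble(
    gsirt_raw = root,
    gsirt = reported,
    gsirt_censored = censored,
    gsirt_label = if (censored) sprintf(">=%.1f", cfg$gsirt_cap)
                  else sprintf("%.1f", reported)
  )
}

#' Derive RAI and GSIR-T for a table of variants
#'
#' Data-frame-first wrapper: takes a tibble of per-variant kinetic
#' parameters, computes RAI and GSIR-T against a wild-type reference and
#' binds the results as new columns.
#'
#' @param params_tbl Tibble with columns `s05`, `n_h`, `kcat`, `km_atp` and
#'   optionally `no_activity` (one row per variant). Rows with missing
#'   parameters and no `no_activity` flag yield `NA` results with a warning.
#' @param wt [kinetic_params()] of the wild type, or `NULL` to use the row
#'   whose `variant` column equals `"WT"`.
#' @param cfg [beta_cell_config()].
#' @return `params_tbl` with `rai`, `rai_censored`, `rai_label`,
#'   `gsirt_raw`, `gsirt`, `gsirt_censored`, `gsirt_label` appended.
#' @export
derive_rai_gsirt <- function(params_tbl, wt = NULL, cfg = beta_cell_config()) {
  stopifnot(is.data.frame(params_tbl))
  if (is.null(wt)) {
    i <- which(params_tbl$variant == "WT")
    if (length(i) != 1) abort("no unique WT row; supply `wt` explicitly")
    wt <- .as_params(params_tbl[i, ])
  }
  res <- purrr::pmap(
    list(params_tbl$s05, params_tbl$n_h, params_tbl$kcat,
         params_tbl$km_atp %||% rep(0, nrow(params_tbl)),
         params_tbl$no_activity %||% rep(FALSE, nrow(params_tbl))),
    function(s05, n_h, kcat, km_atp, no_activity) {
      if (!no_activity && (is.na(s05) || is.na(n_h) || is.na(kcat) ||
                           is.na(km_atp))) {
        warn("incomplete kinetic parameters without no_activity flag; NA result")
        return(tibble::tibble(
          rai = NA_real_, rai_censored = NA, rai_label = NA_character_,
          gsirt_raw = NA_real_, gsirt = NA_real_, gsirt_censored = NA,
          gsirt_label = NA_character_))
      }
      p <- kinetic_params(s05, n_h, kcat, km_atp, no_activity = no_activity)
      dplyr::bind_cols(compute_rai(p, wt, cfg), gsir_threshold(p, wt, cfg))
    }
  )
  dplyr::bind_cols(params_tbl, dplyr::bind_rows(res))
}
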