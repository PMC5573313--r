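# Nonlinear fits for titration assays: Hill (glucose), Michaelis (ATP) and
# four-parameter logistic inhibition (GlcNAc IC50). All fits go through
# minpack.lm::nlsLM (Levenberg-Marquardt with box bounds).

.check_assay <- function(assay, min_x = 5) {
  stopifnot(is.data.frame(assay), all(c("x", "rate") %in% names(assay)))
  assay <- dplyr::filter(assay, is.finite(.data$x), is.finite(.data$rate))
  if (any(assay$x < 0) || any(assay$rate < 0)) {
    abort("concentrations and rates must be non-negative")
  }
  if (length(unique(assay$x)) < min_x) {
    abort(sprintf("need at least %d distinct concentrations", min_x))
  }
  assay
}

.fit_result <- function(fit, data, kind, extra = list()) {
  s <- summary(fit)$coefficients
  est <- tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"]
  )
  structure(
    c(list(estimates = est, fit = fit, data = data, kind = kind,
           converged = fit$convInfo$isConv %||% TRUE,
           no_activity = FALSE, censored = FALSE),
      extra),
    class = c(paste0(sub("_.*", "", kind), "_fit"), "glucovar_fit")
  )
}

#' Fit the Hill equation to a glucose titration
#'
#' Fits `rate = vmax * x^n_h / (s05^n_h + x^n_h)` by Levenberg-Marquardt
#' least squares. Starting values: `s05` at the concentration nearest
#' half-maximal observed rate, `n_h = 1.5`, `vmax` at the maximal rate;
#' `n_h` is bounded to [0.5, 4]. When an enzyme concentration is supplied,
#' `vmax` is converted to a turnover number `kcat`.
#'
#' If the maximal observed rate falls below the detection limit (twice the
#' blank standard deviation, when supplied) or all rates are zero, no model
#' is fitted and the result carries the `no_activity` censor flag.
#'
#' @param assay Tibble with columns `x` (glucose, mM) and `rate` (1/s);
#'   at least 5 distinct concentrations.
#' @param enzyme_conc Optional enzyme concentration in the same rate units,
#'   used to convert `vmax` to `kcat` (`kcat = vmax / enzyme_conc`).
#' @param blank_sd Optional standard deviation of blank measurements
#'   defining the detection limit `2 * blank_sd`.
#' @return Object of class `hill_fit` with `estimates` (tibble of `s05`,
#'   `n_h`, `vmax` with standard errors), `kcat`, `converged`,
#'   `no_activity`; supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_hill <- function(assay, enzyme_conc = NULL, blank_sd = NULL) {
  assay <- .check_assay(assay)
  detection <- if (!is.null(blank_sd)) 2 * blank_sd else 0
  if (max(assay$rate) <= detection) {
    return(structure(list(estimates = NULL, fit = NULL, data = assay,
                          kind = "hill", converged = NA,
                          no_activity = TRUE, censored = TRUE, kcat = NA_real_),
                     class = c("hill_fit", "glucovar_fit")))
  }
  vmax0 <- max(assay$rate)
  s05_0 <- assay$x[which.min(abs(assay$rate - vmax0 / 2))]
  if (s05_0 <= 0) s05_0 <- stats::median(assay$x[assay$x > 0])
  fit <- minpack.lm::nlsLM(
    rate ~ vmax * x^n_h / (s05^n_h + x^n_h),
    data = assay,
    start = list(s05 = s05_0, n_h = 1.5, vmax = vmax0),
    lower = c(s05 = 1e-6, n_h = 0.5, vmax = 1e-12),
    upper = c(s05 = Inf, n_h = 4, vmax = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  kcat <- if (!is.null(enzyme_conc)) unname(coef(fit)["vmax"]) / enzyme_conc
          else NA_real_
  .fit_result(fit, assay, "hill", list(kcat = kcat))
}

#' Fit the Michaelis-Menten equation to an ATP titration
#'
#' Fits `rate = vmax * x / (km_atp + x)` at a stated fixed glucose
#' concentration.
#'
#' @param assay Tibble with columns `x` (ATP, mM) and `rate` (1/s); at least
#'   5 distinct concentrations.
#' @param glucose_mM Fixed glucose concentration of the assay, recorded in
#'   the result.
#' @return Object of class `mm_fit` (see [fit_hill()] for the interface).
#' @export
fit_michaelis <- function(assay, glucose_mM = NA_real_) {
  assay <- .check_assay(assay)
  if (max(assay$rate) <= 0) abort("all rates are zero; nothing to fit")
  vmax0 <- max(assay$rate)
  km0 <- assay$x[which.min(abs(assay$rate - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(assay$x[assay$x > 0])
  fit <- minpack.lm::nlsLM(
    rate ~ vmax * x / (km_atp + x),
    data = assay,
    start = list(km_atp = km0, vmax = vmax0),
    lower = c(km_atp = 1e-9, vmax = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  .fit_result(fit, assay, "mm", list(glucose_mM = glucose_mM))
}

#' Fit a four-parameter logistic inhibition curve and extract the IC50
#'
#' Fits `rate = bottom + (top - bottom) / (1 + (x / ic50)^h)` with `top`
#' constrained to the mean uninhibited rate at dose 0. If the rates do not
#' decrease with dose (no detectable inhibition), the result is censored as
#' a greater-than bound at the highest tested dose.
#'
#' @param assay Tibble with columns `x` (inhibitor, uM; must include 0) and
#'   `rate` (1/s); at least 5 distinct doses.
#' @return Object of class `ic50_fit` with `ic50`, `censored` (TRUE for a
#'   greater-than bound) and the usual fit fields.
#' @export
fit_ic50 <- function(assay) {
  assay <- .check_assay(assay)
  if (!any(assay$x == 0)) abort("inhibitor titration must include dose 0")
  top <- mean(assay$rate[assay$x == 0])
  pos <- dplyr::filter(assay, .data$x > 0)
  trend <- suppressWarnings(cor(pos$x, pos$rate, method = "spearman"))
  if (!is.finite(trend) || trend >= 0 || min(pos$rate) > 0.9 * top) {
    return(structure(list(estimates = NULL, fit = NULL, data = assay,
                          kind = "ic50", converged = NA, no_activity = FALSE,
                          censored = TRUE, ic50 = max(assay$x), top = top),
                     class = c("ic50_fit", "glucovar_fit")))
  }
  ic50_0 <- pos$x[which.min(abs(pos$rate - top / 2))]
  fit <- minpack.lm::nlsLM(
    rate ~ bottom + (top - bottom) / (1 + (x / ic50)^h),
    data = assay,
    start = list(bottom = min(assay$rate), ic50 = ic50_0, h = 1),
    lower = c(bottom = 0, ic50 = 1e-9, h = 0.2),
    upper = c(bottom = top, ic50 = Inf, h = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  .fit_result(fit, assay, "ic50",
              list(ic50 = unname(coef(fit)["ic50"]), top = top))
}

#' @export
print.glucovar_fit <- function(x, ...) {
  cat(sprintf("<%s>", class(x)[1]),
      if (isTRUE(x$no_activity)) "no activity (censored)"
      else if (isTRUE(x$censored)) "censored"
      else "", "\n")
  if (!is.null(x$estimates)) print(x$estimates)
  invisible(x)
}

#' Tidy the coefficients of a kinetic fit
#'
#' @param x A `hill_fit`, `mm_fit` or `ic50_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std_error` (empty for
#'   censored fits).
#' @method tidy glucovar_fit
#' @export
tidy.glucovar_fit <- function(x, ...) {
  x$estimates %||%
    tibble::tibble(term = character(), estimate = numeric(),
                   std_error = numeric())
}

#' One-row model summary of a kinetic fit
#'
#' @param x A `hill_fit`, `mm_fit` or `ic50_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `kind`, `converged`, `no_activity`, `censored`,
#'   `sigma` (residual standard error), `n`.
#' @method glance glucovar_fit
#' @export
glance.glucovar_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    converged = x$converged,
    no_activity = isTRUE(x$no_activity),
    censored = isTRUE(x$censored),
    sigma = if (is.null(x$fit)) NA_real_ else summary(x$fit)$sigma,
    n = nrow(x$data)
  )
}

#' Plot a kinetic fit with its data
#'
#' @param object A `hill_fit`, `mm_fit` or `ic50_fit` object.
#' @param ... Unused.
#' @return A ggplot: observed rates and, for uncensored fits, the fitted
#'   curve over the concentration range (log-spaced for inhibition curves).
#' @method autoplot glucovar_fit
#' @export
autoplot.glucovar_fit <- function(object, ...) {
  lab <- switch(object$kind,
                hill = "glucose [mM]", mm = "ATP [mM]",
                ic50 = "inhibitor [uM]", "x")
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab, y = "rate [1/s]") +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    xr <- range(object$data$x)
    grid <- if (object$kind == "ic50" && xr[1] == 0) {
      c(0, exp(seq(log(max(xr[1], min(object$data$x[object$data$x > 0]))),
                   log(xr[2]), length.out = 100)))
    } else {
      seq(xr[1], xr[2], length.out = 200)
    }
    pred <- tibble::tibble(
      x = grid,
      rate = stats::predict(object$fit, newdata = data.frame(x = grid))
    )
    p <- p + ggplot2::geom_line(data = pred, colour = "steelblue")
  }
  p
}
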