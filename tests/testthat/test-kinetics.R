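wt_params <- function() kinetic_params(s05 = 8.82, n_h = 1.72, kcat = 43.8,
                                       km_atp = 0.36)

glucose_grid <- c(0.5, 1, 2, 5, 10, 20, 40, 80, 150)

test_that("activity obeys half-saturation, zero-glucose and bound limits", {
  p <- kinetic_params(s05 = 8, n_h = 1.7, kcat = 50, km_atp = 0)
  expect_equal(activity(p, glucose = 8, atp = 2.5), 25)
  expect_identical(activity(p, glucose = 0, atp = 2.5), 0)
  g <- seq(0, 100, by = 0.5)
  a <- activity(wt_params(), g, atp = 2.5)
  expect_true(all(diff(a) > 0))       # monotone in glucose
  expect_true(all(a < 43.8))          # bounded by kcat
  a1 <- activity(wt_params(), 5, atp = 1)
  a2 <- activity(wt_params(), 5, atp = 3)
  expect_gt(a2, a1)                   # monotone in ATP
})

test_that("activity matches a direct arithmetic evaluation for WT", {
  # restated term by term, independent of the package's vectorized form
  s05 <- 8.82; n_h <- 1.72; kcat <- 43.8; km <- 0.36
  hand <- kcat * (5^n_h / (s05^n_h + 5^n_h)) * (2.5 / (2.5 + km))
  expect_equal(activity(wt_params(), 5, 2.5), hand, tolerance = 1e-15)
})

test_that("fit_hill recovers noiseless parameters to high precision", {
  truth <- list(s05 = 12.4, n_h = 1.6, vmax = 31)
  assay <- tibble::tibble(
    x = glucose_grid,
    rate = oracle_hill(glucose_grid, truth$s05, truth$n_h, truth$vmax))
  fit <- fit_hill(assay)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["s05"]), truth$s05, tolerance = 1e-6)
  expect_equal(unname(est["n_h"]), truth$n_h, tolerance = 1e-6)
  expect_equal(unname(est["vmax"]), truth$vmax, tolerance = 1e-6)
})

test_that("fit_hill is scale-equivariant in vmax", {
  assay <- tibble::tibble(
    x = glucose_grid, rate = oracle_hill(glucose_grid, 9, 1.7, 10))
  f1 <- fit_hill(assay)
  f2 <- fit_hill(dplyr::mutate(assay, rate = rate * 7))
  e1 <- setNames(tidy(f1)$estimate, tidy(f1)$term)
  e2 <- setNames(tidy(f2)$estimate, tidy(f2)$term)
  expect_equal(unname(e2["vmax"]), unname(7 * e1["vmax"]), tolerance = 1e-6)
  expect_equal(unname(e2["s05"]), unname(e1["s05"]), tolerance = 1e-6)
  expect_equal(unname(e2["n_h"]), unname(e1["n_h"]), tolerance = 1e-6)
})

test_that("noisy Hill fits agree with a coarse grid-search oracle", {
  truth <- list(s05 = 10, n_h = 1.7, vmax = 40)
  assay <- gen_assay(kinetic_params(truth$s05, truth$n_h, truth$vmax, 0),
                     x = glucose_grid, atp_mM = 1e9, replicates = 3,
                     noise_sd = 0.02, seed = 81)
  fit <- fit_hill(assay)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  se <- setNames(tidy(fit)$std_error, tidy(fit)$term)
  for (term in c("s05", "n_h", "vmax")) {
    expect_lt(abs(est[term] - truth[[term]]), 3 * se[term] + 1e-9)
  }
  grid <- oracle_hill_grid(assay$x, assay$rate,
                           s05_grid = seq(5, 20, by = 0.1),
                           nh_grid = seq(1, 2.5, by = 0.02))
  sse_fit <- sum(residuals(fit$fit)^2)
  expect_lte(sse_fit, grid$sse * 1.01)
  expect_gt(sse_fit, grid$sse * 0.99 - 1e-9)
})

test_that("undetectable activity yields the no_activity censor flag", {
  flat <- tibble::tibble(x = glucose_grid, rate = rep(0, length(glucose_grid)))
  fit <- fit_hill(flat)
  expect_true(fit$no_activity)
  expect_null(fit$estimates)
  near_blank <- tibble::tibble(x = glucose_grid, rate = rep(0.001, 9))
  expect_true(fit_hill(near_blank, blank_sd = 0.01)$no_activity)
})

test_that("fit_michaelis recovers noiseless ATP kinetics", {
  x <- c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5)
  assay <- tibble::tibble(x = x, rate = 30 * x / (0.45 + x))
  fit <- fit_michaelis(assay, glucose_mM = 50)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["km_atp"]), 0.45, tolerance = 1e-6)
  expect_equal(unname(est["vmax"]), 30, tolerance = 1e-6)
  expect_equal(fit$glucose_mM, 50)
  expect_error(fit_michaelis(tibble::tibble(x = 1, rate = 5)), "at least 5")
})

test_that("fit_ic50 recovers a noiseless inhibition curve and censors", {
  x <- c(0, 10, 50, 100, 250, 500, 1000, 2500)
  rate <- 12 + (40 - 12) / (1 + (x / 220)^1.3)
  rate[x == 0] <- 40
  fit <- fit_ic50(tibble::tibble(x = x, rate = rate))
  expect_equal(fit$ic50, 220, tolerance = 1e-4)
  expect_false(fit$censored)
  up <- tibble::tibble(x = x, rate = 40 + 0.01 * x)
  cen <- fit_ic50(up)
  expect_true(cen$censored)
  expect_equal(cen$ic50, 2500)  # greater-than bound at the top dose
  expect_error(fit_ic50(tibble::tibble(x = c(1, 2, 3, 4, 5), rate = 1:5)),
               "dose 0")
})

test_that("stability index is a simple percentage of the control", {
  expect_equal(stability_index(10, 10), 100)
  expect_equal(stability_index(5, 10), 50)
  expect_equal(stability_index(86, 100), 86)
  expect_error(stability_index(5, 0), "positive")
})

test_that("RAI is 1 for wild type and censored for inactive alleles", {
  wt <- wt_params()
  expect_equal(compute_rai(wt, wt)$rai, 1)
  dead <- kinetic_params(NA, NA, NA, no_activity = TRUE)
  res <- compute_rai(dead, wt)
  expect_true(res$rai_censored)
  expect_equal(res$rai_label, "<0.01")
  expect_error(compute_rai(wt, dead), "wild type")
})

test_that("GSIR-T returns the setpoint for wild type and censors null alleles", {
  wt <- wt_params()
  res <- gsir_threshold(wt, wt)
  expect_identical(res$gsirt_raw, 5)
  dead <- kinetic_params(NA, NA, NA, no_activity = TRUE)
  cen <- gsir_threshold(dead, wt)
  expect_true(cen$gsirt_censored)
  expect_equal(cen$gsirt_label, ">=7.1")
})

test_that("bisection agrees with the dense grid-scan oracle", {
  wt <- wt_params()
  cfg <- beta_cell_config()
  # a mildly inactivating variant with a root inside the reporting range
  c252r <- kinetic_params(8.37, 1.61, 11.8, 0.27)
  bis <- gsir_threshold(c252r, wt, cfg)$gsirt_raw
  grid <- oracle_gsirt_grid(c252r, wt, cfg)
  expect_lt(abs(bis - grid), 1e-3 + cfg$tol)
  # an activating variant roots below the setpoint
  r63s <- kinetic_params(4.44, 1.64, 57.7, 0.23)
  expect_lt(abs(gsir_threshold(r63s, wt, cfg)$gsirt_raw -
                  oracle_gsirt_grid(r63s, wt, cfg)), 1e-3 + cfg$tol)
})

test_that("GSIR-T moves monotonically with catalytic capacity", {
  wt <- wt_params()
  kcats <- c(5, 10, 20, 43.8, 60, 90)
  roots <- vapply(kcats, function(k) {
    gsir_threshold(kinetic_params(8.82, 1.72, k, 0.36), wt)$gsirt_raw
  }, numeric(1))
  expect_true(all(diff(roots) <= 1e-9))  # more activity, lower threshold
})

test_that("RAI above one coincides with a threshold below the setpoint", {
  wt <- wt_params()
  set.seed(19)
  for (i in 1:25) {
    p <- kinetic_params(runif(1, 3, 40), runif(1, 1, 2.2),
                        runif(1, 5, 80), runif(1, 0.1, 1.5))
    rai <- compute_rai(p, wt)$rai
    gs <- gsir_threshold(p, wt)$gsirt_raw
    if (is.na(gs)) next
    if (abs(rai - 1) > 1e-6) {
      expect_identical(rai > 1, gs < 5)
    }
  }
})

test_that("derived RAI/GSIR-T track the reported reference table ordinally", {
  tab <- suppressWarnings(derive_rai_gsirt(gck_kinetic_table()))
  comp <- dplyr::filter(tab, variant != "WT", !is.na(rai), !is.na(rai_reported))
  expect_gte(nrow(comp), 13)
  expect_gte(cor(comp$rai, comp$rai_reported, method = "spearman"), 0.9)
  g <- dplyr::filter(tab, variant != "WT", !is.na(gsirt), !is.na(gsirt_reported))
  expect_gte(cor(g$gsirt, g$gsirt_reported, method = "spearman"), 0.8)
})

test_that("fit objects expose broom-style and plotting interfaces", {
  assay <- tibble::tibble(x = glucose_grid,
                          rate = oracle_hill(glucose_grid, 9, 1.7, 20))
  fit <- fit_hill(assay)
  expect_named(tidy(fit), c("term", "estimate", "std_error"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, length(glucose_grid))
  expect_s3_class(autoplot(fit), "ggplot")
})
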