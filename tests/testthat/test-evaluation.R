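test_that("GSIR-T binning places boundaries in the normal range", {
  expect_equal(as.character(bin_gsirt(c(3.9, 4, 5.5, 5.6))),
               c("low", "normal", "normal", "high"))
  expect_equal(as.character(bin_gsirt(7.1, censored = TRUE)), "high")
  expect_error(bin_gsirt(-1), "negative")
})

test_that("Hill-coefficient binning matches the cooperativity classes", {
  expect_equal(as.character(bin_hill(c(1.0, 1.2, 1.5, 1.72))),
               c("lt_1.2", "1.2_1.5", "1.2_1.5", "gt_1.5"))
  expect_error(bin_hill(-0.1), "negative")
})

test_that("class metrics reproduce direct counts on a toy set", {
  classes <- rep(c("MODY", "normoglycemic"), c(10, 4))
  calls <- c(rep(TRUE, 7), rep(FALSE, 3),   # 7/10 MODY called deleterious
             TRUE, TRUE, TRUE, FALSE)        # 1/4 neutral called neutral
  m <- class_metrics(classes, calls, "phenotype")
  by <- tidy(m)
  expect_equal(by$sensitivity_pct[by$class == "MODY"], 70)
  expect_equal(by$sensitivity_pct[by$class == "normoglycemic"], 25)
  expect_equal(m$false_positive_ratio, 30)
})

test_that("a perfect predictor scores 100 percent everywhere", {
  classes <- c(rep("MODY", 5), rep("PHHI", 3), rep("normoglycemic", 4))
  calls <- c(rep(TRUE, 8), rep(FALSE, 4))
  m <- class_metrics(classes, calls, "phenotype")
  expect_true(all(tidy(m)$sensitivity_pct == 100))
  expect_equal(m$false_positive_ratio, 0)
})

test_that("missing calls leave denominators and are reported", {
  classes <- rep("MODY", 4)
  calls <- c(TRUE, NA, NA, FALSE)
  m <- class_metrics(classes, calls, "phenotype")
  by <- tidy(m)
  expect_equal(by$n, 2)
  expect_equal(by$n_missing, 2)
  expect_equal(by$sensitivity_pct, 50)
})

test_that("class metrics match the loop-based oracle on random sets", {
  set.seed(67)
  for (i in 1:200) {
    grouping <- sample(c("phenotype", "gsirt", "hill"), 1)
    expected <- glucovar:::.expected_calls[[grouping]]
    n <- sample(5:60, 1)
    classes <- sample(names(expected), n, replace = TRUE)
    calls <- sample(c(TRUE, FALSE, NA), n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    m <- suppressWarnings(class_metrics(classes, calls, grouping))
    o <- oracle_class_metrics(classes, calls, expected)
    by <- tidy(m)
    for (cl in names(o$by_class)) {
      row <- by[by$class == cl, ]
      expect_equal(row$sensitivity_pct, round(o$by_class[[cl]]$sens, 1))
    }
    if (!is.na(o$fp)) expect_equal(m$false_positive_ratio, round(o$fp, 1))
  }
})

test_that("agreement counts tally calling methods per variant", {
  calls <- tibble::tibble(a = c(TRUE, FALSE, NA), b = c(TRUE, FALSE, TRUE),
                          c = c(TRUE, FALSE, NA))
  res <- agreement_counts(calls)
  expect_equal(res$n_effect, c(3, 0, 1))
  expect_equal(res$n_scored, c(3, 3, 1))
})

test_that("substitution enumeration is exhaustive and deterministic", {
  expect_equal(nrow(enumerate_substitutions("M")), 19)
  expect_equal(nrow(enumerate_substitutions(character(0))), 0)
  set.seed(71)
  for (L in sample(1:600, 8)) {
    seqc <- sample(glucovar:::AA_ALPHABET, L, replace = TRUE)
    en <- enumerate_substitutions(seqc)
    expect_equal(nrow(en), 19 * L)
    expect_true(all(en$ref_aa != en$alt_aa))
    # lexicographic (position, alt) order
    expect_identical(en, dplyr::arrange(en, position, alt_aa))
  }
  expect_error(enumerate_substitutions("MXT"), "position 2")
})

test_that("score summaries use interpolated quartiles", {
  s <- score_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$se, sd(c(1, 2, 3)) / sqrt(3))
  one <- score_summary(5)
  expect_equal(one$min, 5)
  expect_equal(one$max, 5)
  expect_equal(one$median, 5)
  # uniform grid 0..100: closed-form type-7 quartiles
  g <- score_summary(0:100)
  expect_equal(g$q25, 25)
  expect_equal(g$q75, 75)
  expect_error(score_summary(NA_real_), "finite")
})

test_that("score correlations handle monotone maps and missing pairs", {
  d <- tibble::tibble(a = 1:20, b = (1:20)^3)
  r <- score_correlations(d, a, b)
  expect_equal(r$spearman, 1)
  expect_lt(r$pearson, 1)
  d2 <- tibble::tibble(a = c(1:10, NA), b = c(1:10, 5))
  expect_equal(score_correlations(d2, a, b)$n, 10)
  set.seed(73)
  n <- 4000
  z <- rnorm(n)
  d3 <- tibble::tibble(a = z, b = -0.778 * z + sqrt(1 - 0.778^2) * rnorm(n))
  expect_equal(score_correlations(d3, a, b)$pearson, -0.778, tolerance = 0.05)
})

test_that("ternary coordinates are compositional and orientation-harmonized", {
  set.seed(79)
  d <- tibble::tibble(evmutation = rnorm(200, -5, 2),
                      popmusic_ddg = rnorm(200, 1, 0.5),
                      snap2 = rnorm(200, 0, 40))
  t <- harmonize_ternary(d)
  expect_true(all(abs(t$t_ev + t$t_pop + t$t_snap - 1) < 1e-12))
  expect_true(all(t$t_ev >= 0 & t$t_pop >= 0 & t$t_snap >= 0))
  # maximal-deleterious triple sits at the barycenter
  dmax <- tibble::tibble(evmutation = c(-10, 0), popmusic_ddg = c(3, 0),
                         snap2 = c(90, -99))
  tm <- harmonize_ternary(dmax)
  expect_equal(unlist(tm[1, c("t_ev", "t_pop", "t_snap")]),
               c(t_ev = 1 / 3, t_pop = 1 / 3, t_snap = 1 / 3))
  # all-zero harmonized triple maps to the barycenter too
  expect_equal(unlist(tm[2, c("t_ev", "t_pop", "t_snap")]),
               c(t_ev = 1 / 3, t_pop = 1 / 3, t_snap = 1 / 3))
})

test_that("ternary coordinates are invariant to common positive rescaling", {
  set.seed(83)
  d <- tibble::tibble(evmutation = rnorm(50, -5, 2),
                      popmusic_ddg = rnorm(50, 1, 0.5),
                      snap2 = rnorm(50, 0, 40))
  t1 <- harmonize_ternary(d)
  scale <- 3.7
  d2 <- dplyr::mutate(d, evmutation = evmutation * scale,
                      popmusic_ddg = popmusic_ddg * scale,
                      snap2 = snap2 * scale)
  t2 <- harmonize_ternary(d2)
  expect_equal(t2$t_ev, t1$t_ev, tolerance = 1e-12)
  expect_equal(t2$t_pop, t1$t_pop, tolerance = 1e-12)
  expect_equal(t2$t_snap, t1$t_snap, tolerance = 1e-12)
})

test_that("rows missing one of the three scores are dropped with a message", {
  d <- tibble::tibble(evmutation = c(-5, NA, -3), popmusic_ddg = c(1, 1, 2),
                      snap2 = c(10, 20, 30))
  expect_message(t <- harmonize_ternary(d), "1 row")
  expect_equal(nrow(t), 2)
})

test_that("region classifier follows the score-plane definitions strictly", {
  expect_equal(as.character(region_classify(-8, 75)),
               "putatively_highly_pathogenic")
  expect_equal(as.character(region_classify(-3, -60)), "putatively_benign")
  expect_equal(as.character(region_classify(-7.5, 80)), "other")  # boundary
  expect_equal(as.character(region_classify(-8, 70)), "other")    # boundary
  expect_equal(as.character(region_classify(-2, -60)), "putatively_benign")
  expect_equal(as.character(region_classify(-3, -50)), "other")   # boundary
  expect_true(is.na(region_classify(NA, 10)))
  # regions partition the plane: every point gets exactly one label
  set.seed(89)
  cls <- region_classify(runif(500, -12, 5), runif(500, -100, 100))
  expect_true(all(!is.na(cls)))
})
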