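# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computation paths.

# Grantham 1974 constants and properties, restated locally
.oracle_props <- function() {
  list(
    c = c(A = 0, R = 0.65, N = 1.33, D = 1.38, C = 2.75, Q = 0.89, E = 0.92,
          G = 0.74, H = 0.58, I = 0, L = 0, K = 0.33, M = 0, F = 0, P = 0.39,
          S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0),
    p = c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
          G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
          P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9),
    v = c(A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83, G = 3,
          H = 96, I = 111, L = 111, K = 119, M = 105, F = 132, P = 32.5,
          S = 32, T = 61, W = 170, Y = 136, V = 84)
  )
}

# GV by direct range arithmetic over the observed residue set
oracle_gv <- function(residues) {
  pr <- .oracle_props()
  res <- unique(residues)
  term <- function(w, prop) w * (max(prop[res]) - min(prop[res]))^2
  50.723 * sqrt(term(1.833, pr$c) + term(0.1018, pr$p) + term(0.000399, pr$v))
}

# GD by direct range-deviation arithmetic
oracle_gd <- function(residues, mutant) {
  pr <- .oracle_props()
  res <- unique(residues)
  dev <- function(prop) {
    lo <- min(prop[res]); hi <- max(prop[res]); x <- prop[[mutant]]
    max(0, lo - x, x - hi)
  }
  50.723 * sqrt(1.833 * dev(pr$c)^2 + 0.1018 * dev(pr$p)^2 +
                0.000399 * dev(pr$v)^2)
}

# Hill curve evaluated pointwise (restated, not via activity())
oracle_hill <- function(x, s05, n_h, vmax) {
  vmax * x^n_h / (s05^n_h + x^n_h)
}

# coarse grid search for Hill parameters with vmax profiled analytically
oracle_hill_grid <- function(x, y, s05_grid, nh_grid) {
  best <- list(sse = Inf)
  for (s in s05_grid) for (n in nh_grid) {
    h <- x^n / (s^n + x^n)
    v <- sum(y * h) / sum(h^2)
    sse <- sum((y - v * h)^2)
    if (sse < best$sse) best <- list(s05 = s, n_h = n, vmax = v, sse = sse)
  }
  best
}

# GSIR-T by dense grid scan (1e-3 mM): first glucose where the heterozygous
# combined rate reaches the wild-type setpoint rate
oracle_gsirt_grid <- function(var, wt, cfg = beta_cell_config(),
                              g_max = 500, step = 1e-3) {
  g <- seq(step, g_max, by = step)
  a <- function(p, gg) {
    if (isTRUE(p$no_activity)) return(rep(0, length(gg)))
    p$kcat * gg^p$n_h / (p$s05^p$n_h + gg^p$n_h) *
      cfg$atp_conc / (cfg$atp_conc + p$km_atp)
  }
  target <- a(wt, cfg$g_ref)
  f <- cfg$het_fraction * cfg$compensation * a(wt, g) +
    cfg$het_fraction * a(var, g) - target
  i <- which(f >= 0)[1]
  if (is.na(i)) return(NA_real_)
  g[i]
}

# confusion-count metrics by explicit loops
oracle_class_metrics <- function(classes, deleterious, expected) {
  out <- list()
  for (cl in intersect(unique(classes), names(expected))) {
    idx <- which(classes == cl & !is.na(deleterious))
    if (length(idx) == 0) next
    match_call <- if (expected[[cl]] == "deleterious") {
      deleterious[idx]
    } else {
      !deleterious[idx]
    }
    out[[cl]] <- list(n = length(idx), sens = 100 * sum(match_call) / length(idx))
  }
  dis <- which(classes %in% names(expected)[expected == "deleterious"] &
                 !is.na(deleterious))
  fp <- if (length(dis) > 0) 100 * sum(!deleterious[dis]) / length(dis)
        else NA_real_
  list(by_class = out, fp = fp)
}

# sort-based median and two-pass sample SD, restated
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}
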