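# Synthetic-data generators with known ground truth: Hill-structured assays,
# class-conditional predictor score tables, alignments with controlled
# conservation, and GV-coupled family counts.

#' Simulate a titration assay from known kinetic parameters
#'
#' Draws rates on the model curve of [activity()] plus Gaussian noise with
#' standard deviation `noise_sd` times the curve's asymptotic maximum,
#' truncated at zero. With `noise_sd = 0` the rates lie exactly on the
#' curve, so the fit_* functions recover the generating parameters.
#'
#' @param params [kinetic_params()] of the simulated enzyme form.
#' @param x Concentration grid: glucose (mM) for `glucose_titration`, ATP
#'   (mM) for `atp_titration`.
#' @param kind `"glucose_titration"` or `"atp_titration"`.
#' @param atp_mM Fixed ATP concentration for glucose titrations.
#' @param glucose_mM Fixed glucose concentration for ATP titrations.
#' @param replicates Number of replicate curves.
#' @param noise_sd Noise standard deviation as a fraction of the asymptotic
#'   maximal rate (e.g. 0.02 = 2 percent).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return Tibble with columns `assay_kind`, `replicate`, `x`, `rate`,
#'   `glucose_mM`, `atp_mM`.
#' @export
gen_assay <- function(params, x, kind = c("glucose_titration", "atp_titration"),
                      atp_mM = 5, glucose_mM = 50, replicates = 3,
                      noise_sd = 0.02, seed = NULL) {
  kind <- arg_match(kind)
  params <- .as_params(params)
  stopifnot(all(x >= 0), replicates >= 1, noise_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  if (kind == "glucose_titration") {
    mu <- activity(params, x, atp_mM)
    vmax <- params$kcat * atp_mM / (atp_mM + params$km_atp)
    fixed <- list(glucose_mM = NA_real_, atp_mM = atp_mM)
  } else {
    mu <- vapply(x, function(a) activity(params, glucose_mM, a), numeric(1))
    vmax <- activity(params, glucose_mM, 1e9)
    fixed <- list(glucose_mM = glucose_mM, atp_mM = NA_real_)
  }
  out <- purrr::map(seq_len(replicates), function(r) {
    rate <- pmax(0, mu + rnorm(length(mu), 0, noise_sd * vmax))
    tibble::tibble(assay_kind = kind, replicate = r, x = x, rate = rate,
                   glucose_mM = fixed$glucose_mM, atp_mM = fixed$atp_mM)
  })
  dplyr::bind_rows(out)
}

#' Default class-conditional score distributions
#'
#' Normal score distributions per predictor and phenotype class used by
#' [gen_variant_table()]. The neutral (normoglycemic) class is
#' parameterized from reported summary statistics of neutral GCK variants
#' (EVmutation median -2.39, SD 1.96; SNAP2 mean -58, SD 32.25; PoPMuSiC
#' median 0.58 kcal/mol, SD 0.42), so that evidence-based calibration on
#' large simulated neutral sets recovers the thresholds -6.31, 6.5 and
#' 1.42. Disease-class parameters are plausible placeholders (they are not
#' derived from published statistics) chosen to mimic the qualitative
#' separation seen between classes.
#'
#' @return Tibble with columns `predictor`, `class`, `mean`, `sd`,
#'   `missingness`.
#' @export
score_spec <- function() {
  tibble::tribble(
    ~predictor,     ~class,          ~mean,  ~sd,   ~missingness,
    "evmutation",   "normoglycemic", -2.39,  1.96,  0.05,
    "evmutation",   "MODY",          -6.5,   1.8,   0.05,
    "evmutation",   "PHHI",          -3.5,   1.6,   0.05,
    "evmutation",   "unknown",       -5.35,  2.4,   0.07,
    "popmusic_ddg", "normoglycemic",  0.58,  0.42,  0.1,
    "popmusic_ddg", "MODY",           1.45,  0.75,  0.1,
    "popmusic_ddg", "PHHI",           0.9,   0.6,   0.1,
    "popmusic_ddg", "unknown",        1.10,  0.85,  0.1,
    "snap2",        "normoglycemic", -58,    32.25, 0.02,
    "snap2",        "MODY",           40,    30,    0.02,
    "snap2",        "PHHI",           15,    35,    0.02,
    "snap2",        "unknown",        4.5,   55,    0.05
  )
}

#' Simulate a labeled variant table with class-conditional scores
#'
#' Draws variants (random positions and substitutions on a reference of
#' length `L`) per phenotype class, with predictor scores drawn from the
#' class-conditional Normal distributions of `spec` and missingness applied
#' per predictor. Class sizes default to the composition of the curated GCK
#' variant sets (499 MODY, 16 PHHI, 53 normoglycemic).
#'
#' @param n_per_class Named integer vector of class sizes.
#' @param spec Distribution spec, see [score_spec()].
#' @param L Reference protein length.
#' @param seed Optional integer seed.
#' @return Tibble with `variant`, `position`, `ref_aa`, `alt_aa`,
#'   `phenotype` and one column per predictor in `spec`; attribute
#'   `manifest` records the generating arguments.
#' @export
gen_variant_table <- function(n_per_class = c(MODY = 499, PHHI = 16,
                                              normoglycemic = 53),
                              spec = score_spec(), L = 465, seed = NULL) {
  stopifnot(!is.null(names(n_per_class)), all(n_per_class >= 0))
  if (!is.null(seed)) withr::local_seed(seed)
  classes <- rep(names(n_per_class), times = n_per_class)
  n <- length(classes)
  position <- sample.int(L, n, replace = TRUE)
  ref_aa <- sample(AA_ALPHABET, n, replace = TRUE)
  alt_aa <- vapply(ref_aa, function(r) sample(setdiff(AA_ALPHABET, r), 1),
                   character(1))
  out <- tibble::tibble(
    variant = paste0(ref_aa, position, alt_aa),
    position = position, ref_aa = ref_aa, alt_aa = unname(alt_aa),
    phenotype = classes
  )
  for (pred in unique(spec$predictor)) {
    col <- rep(NA_real_, n)
    for (cl in unique(classes)) {
      row <- dplyr::filter(spec, .data$predictor == pred, .data$class == cl)
      if (nrow(row) != 1) next
      idx <- which(classes == cl)
      val <- rnorm(length(idx), row$mean, row$sd)
      val[runif(length(idx)) < row$missingness] <- NA_real_
      col[idx] <- val
    }
    out[[pred]] <- col
  }
  attr(out, "manifest") <- list(n_per_class = as.list(n_per_class), L = L,
                                seed = seed, spec = spec)
  out
}

# default residue pools for variable alignment columns: physicochemically
# close sets typical of tolerated substitutions, plus a few broad ones
.default_pools <- list(
  c("T", "S"), c("V", "I"), c("K", "R"), c("D", "E"), c("L", "I", "V", "M"),
  c("F", "Y"), c("A", "S", "T"), c("N", "S", "D"), c("Q", "E", "K"),
  c("G", "A", "S"), c("F", "Y", "W"), c("H", "Q", "R")
)

#' Simulate a protein alignment with controlled conservation
#'
#' Generates an ungapped alignment of `n_species` sequences of length `L`
#' with exactly `round(L * invariant_fraction)` invariant columns. Each
#' variable column draws its residues from one of the supplied residue
#' pools, resampling until at least two distinct residues are present, so
#' every variable column has a known positive GV. The returned truth table
#' is the generator's ground truth for round-trip tests.
#'
#' @param L Alignment length (reference length; no gaps are generated).
#' @param n_species Number of sequences (default 12).
#' @param invariant_fraction Fraction of invariant columns (default
#'   301/465, the conservation level typical of vertebrate GCK).
#' @param pools List of character vectors of residues for variable columns.
#' @param ref_id Identifier of the first (reference) sequence.
#' @param seed Optional integer seed.
#' @return List with `alignment` (tibble `id`, `seq`) and `truth` (tibble
#'   `position`, `invariant`, `residues` list-column of the distinct
#'   residues present).
#' @export
gen_alignment <- function(L = 465, n_species = 12,
                          invariant_fraction = 301 / 465,
                          pools = NULL, ref_id = "ref_human", seed = NULL) {
  stopifnot(L >= 1, n_species >= 2,
            invariant_fraction >= 0, invariant_fraction <= 1)
  pools <- pools %||% .default_pools
  if (any(lengths(pools) == 0)) abort("empty residue pool")
  if (!is.null(seed)) withr::local_seed(seed)
  n_inv <- round(L * invariant_fraction)
  inv_pos <- sort(sample.int(L, n_inv))
  is_inv <- seq_len(L) %in% inv_pos
  mat <- matrix("", nrow = n_species, ncol = L)
  for (j in seq_len(L)) {
    if (is_inv[j]) {
      mat[, j] <- sample(AA_ALPHABET, 1)
    } else {
      pool <- pools[[sample.int(length(pools), 1)]]
      if (length(unique(pool)) < 2) {
        abort("variable-column pool needs at least 2 distinct residues")
      }
      repeat {
        col <- sample(pool, n_species, replace = TRUE)
        if (length(unique(col)) >= 2) break
      }
      mat[, j] <- col
    }
  }
  ids <- c(ref_id, sprintf("sp%02d", seq_len(n_species - 1) + 1))
  alignment <- tibble::tibble(
    id = ids,
    seq = apply(mat, 1, paste, collapse = "")
  )
  truth <- tibble::tibble(
    position = seq_len(L),
    invariant = is_inv,
    residues = lapply(seq_len(L), function(j) sort(unique(mat[, j])))
  )
  list(alignment = alignment, truth = truth)
}

#' Simulate per-residue disease-family counts coupled to conservation
#'
#' Draws negative-binomial family counts whose log-mean decreases with GV,
#' emulating the empirical pattern that strongly conserved (low-GV) sites
#' accumulate disease-associated families. With `coupling = 0` the counts
#' are independent of GV.
#'
#' @param profile Tibble from [conservation_profile()] (needs `gv`;
#'   unscorable `NA` values are treated as fully conserved, GV 0).
#' @param coupling Decay rate of the log-mean per Grantham unit
#'   (default 0.02).
#' @param base_mean Mean family count at GV 0 (default 3).
#' @param dispersion Negative-binomial size parameter (default 0.6; smaller
#'   = more overdispersed).
#' @param seed Optional integer seed.
#' @return Tibble with `position` and `families` (non-negative integers).
#' @export
gen_family_counts <- function(profile, coupling = 0.02, base_mean = 3,
                              dispersion = 0.6, seed = NULL) {
  stopifnot(is.data.frame(profile), "gv" %in% names(profile))
  if (!is.null(seed)) withr::local_seed(seed)
  g <- ifelse(is.na(profile$gv), 0, profile$gv)
  mu <- base_mean * exp(-coupling * g)
  tibble::tibble(
    position = profile$position,
    families = rnbinom(length(mu), size = dispersion, mu = mu)
  )
}
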