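# Multi-class evaluation of predictor calls against phenotype, GSIR-T and
# Hill-coefficient groupings; agreement counts; saturating enumeration;
# score summaries, correlations, ternary transformation and the 2-D region
# classifier.

#' Bin GSIR-T values into activating / normal / deactivating classes
#'
#' Boundaries 4.0 and 5.5 mM are inclusive in the normal bin. Values
#' censored at the cap (inactive alleles) fall in the high bin.
#'
#' @param gsirt GSIR-T values, mM glucose.
#' @param censored Logical (recycled): TRUE for values censored at the cap.
#' @return Factor with levels `low` (< 4), `normal` (4-5.5), `high` (> 5.5).
#' @export
bin_gsirt <- function(gsirt, censored = FALSE) {
  censored <- rep_len(censored, length(gsirt))
  if (any(gsirt < 0, na.rm = TRUE)) abort("GSIR-T cannot be negative")
  out <- dplyr::case_when(
    censored ~ "high",
    gsirt < 4 ~ "low",
    gsirt <= 5.5 ~ "normal",
    gsirt > 5.5 ~ "high"
  )
  factor(out, levels = c("low", "normal", "high"))
}

#' Bin Hill coefficients into cooperativity-loss classes
#'
#' Boundaries 1.2 and 1.5 are inclusive in the middle bin; the wild-type
#' range (> 1.5) is the normal class.
#'
#' @param n_h Hill coefficients.
#' @return Factor with levels `lt_1.2`, `1.2_1.5`, `gt_1.5`.
#' @export
bin_hill <- function(n_h) {
  if (any(n_h < 0, na.rm = TRUE)) abort("Hill coefficient cannot be negative")
  out <- dplyr::case_when(
    n_h < 1.2 ~ "lt_1.2",
    n_h <= 1.5 ~ "1.2_1.5",
    n_h > 1.5 ~ "gt_1.5"
  )
  factor(out, levels = c("lt_1.2", "1.2_1.5", "gt_1.5"))
}

# Expected call per class under each grouping scheme: disease classes and
# abnormal kinetic bins expect a deleterious call, the neutral phenotype and
# normal-range bins expect a neutral one.
.expected_calls <- list(
  phenotype = c(MODY = "deleterious", PHHI = "deleterious",
                PNDM = "deleterious", normoglycemic = "neutral"),
  gsirt = c(low = "deleterious", normal = "neutral", high = "deleterious"),
  hill = c(lt_1.2 = "deleterious", `1.2_1.5` = "deleterious",
           gt_1.5 = "neutral")
)

#' Per-class sensitivity and false-positive ratio of a predictor
#'
#' Scores one predictor's calls against a grouping of the variants
#' (phenotype, GSIR-T bin or Hill-coefficient bin). Sensitivity of a class
#' is the percentage of its scored members whose call matches the class's
#' expected call (deleterious for disease / abnormal-kinetics classes,
#' neutral for the normoglycemic / normal-range classes). The
#' false-positive ratio is the percentage of scored disease-expectation
#' variants that received a neutral call. Variants without a score are
#' excluded from all denominators and counted in `n_missing`.
#'
#' @param classes Class label per variant (character or factor; `NA`
#'   excluded).
#' @param deleterious Logical call per variant: TRUE = deleterious,
#'   FALSE = neutral / not called, `NA` = no score.
#' @param grouping `"phenotype"`, `"gsirt"` or `"hill"`; selects the
#'   expected-call mapping.
#' @param expected Optional named character vector overriding the mapping
#'   (`"deleterious"` / `"neutral"` per class).
#' @return Object of class `class_metrics`: list with `by_class` (tibble:
#'   `class`, `n`, `n_missing`, `expected`, `sensitivity_pct`),
#'   `false_positive_ratio` (percent), `grouping`. Supports [tidy()] and
#'   [glance()].
#' @export
class_metrics <- function(classes, deleterious,
                          grouping = c("phenotype", "gsirt", "hill"),
                          expected = NULL) {
  grouping <- arg_match(grouping)
  stopifnot(length(classes) == length(deleterious))
  expected <- expected %||% .expected_calls[[grouping]]
  classes <- as.character(classes)
  keep <- !is.na(classes) & classes %in% names(expected)
  cls <- classes[keep]
  del <- deleterious[keep]
  by_class <- tibble::tibble(class = cls, deleterious = del) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = sum(!is.na(.data$deleterious)),
      n_missing = sum(is.na(.data$deleterious)),
      .groups = "drop"
    ) |>
    dplyr::mutate(expected = unname(expected[.data$class]))
  sens <- purrr::map2_dbl(by_class$class, by_class$expected, function(cl, ex) {
    d <- del[cls == cl & !is.na(del)]
    if (length(d) == 0) return(NA_real_)
    100 * mean(if (ex == "deleterious") d else !d)
  })
  by_class$sensitivity_pct <- round(sens, 1)
  disease <- cls %in% names(expected)[expected == "deleterious"] & !is.na(del)
  fp <- if (any(disease)) round(100 * mean(!del[disease]), 1) else NA_real_
  empty <- by_class$class[by_class$n == 0]
  if (length(empty) > 0) {
    warn(sprintf("class(es) with no scored members: %s",
                 paste(empty, collapse = ", ")))
  }
  structure(list(by_class = by_class, false_positive_ratio = fp,
                 grouping = grouping),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("<class_metrics: %s>  false positive ratio %.1f%%\n",
              x$grouping, x$false_positive_ratio))
  print(x$by_class)
  invisible(x)
}

#' @rdname class_metrics
#' @param x A `class_metrics` object.
#' @param ... Unused.
#' @method tidy class_metrics
#' @export
tidy.class_metrics <- function(x, ...) x$by_class

#' @rdname class_metrics
#' @method glance class_metrics
#' @export
glance.class_metrics <- function(x, ...) {
  tibble::tibble(
    grouping = x$grouping,
    n_classes = nrow(x$by_class),
    n_scored = sum(x$by_class$n),
    n_missing = sum(x$by_class$n_missing),
    false_positive_ratio = x$false_positive_ratio
  )
}

#' Count methods agreeing on an effect, per variant
#'
#' For a table of per-method deleterious calls (one column per predictor,
#' logical: TRUE = effect), counts per row how many methods call an effect
#' and how many produced a call at all (missing scores excluded).
#'
#' @param calls Data frame of logical call columns, one row per variant.
#' @return Tibble with `n_effect` and `n_scored` per variant.
#' @export
agreement_counts <- function(calls) {
  stopifnot(is.data.frame(calls))
  m <- as.matrix(dplyr::mutate(calls, dplyr::across(dplyr::everything(),
                                                    as.logical)))
  tibble::tibble(
    n_effect = rowSums(m, na.rm = TRUE),
    n_scored = rowSums(!is.na(m))
  )
}

#' Enumerate all possible single amino-acid substitutions
#'
#' Saturating in-silico mutagenesis: every position of the sequence times
#' the 19 non-reference residues, in deterministic (position, alternate)
#' order.
#'
#' @param sequence Protein sequence (single string of standard one-letter
#'   codes, or character vector of residues).
#' @return Tibble with `position`, `ref_aa`, `alt_aa`, `variant`
#'   (e.g. `"V33A"`); `19 * L` rows.
#' @export
#' @examples
#' nrow(enumerate_substitutions("MKT"))  # 57
enumerate_substitutions <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) != 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (length(sequence) == 0) {
    return(tibble::tibble(position = integer(), ref_aa = character(),
                          alt_aa = character(), variant = character()))
  }
  sequence <- toupper(sequence)
  bad <- which(!sequence %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("non-standard residue %s at position %d",
                  dQuote(sequence[bad[1]], FALSE), bad[1]))
  }
  out <- tidyr::expand_grid(position = seq_along(sequence),
                            alt_aa = AA_ALPHABET) |>
    dplyr::mutate(ref_aa = sequence[.data$position]) |>
    dplyr::filter(.data$alt_aa != .data$ref_aa) |>
    dplyr::arrange(.data$position, .data$alt_aa) |>
    dplyr::mutate(variant = paste0(.data$ref_aa, .data$position, .data$alt_aa)) |>
    dplyr::select("position", "ref_aa", "alt_aa", "variant")
  out
}

#' Descriptive summary of a score vector
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param scores Numeric vector; at least one finite value.
#' @return One-row tibble: `n`, `mean`, `se`, `min`, `max`, `median`,
#'   `q25`, `q75`.
#' @export
score_summary <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0) abort("need at least one finite score")
  tibble::tibble(
    n = length(scores),
    mean = mean(scores),
    se = sd(scores) / sqrt(length(scores)),
    min = min(scores),
    max = max(scores),
    median = median(scores),
    q25 = quantile(scores, 0.25, names = FALSE),
    q75 = quantile(scores, 0.75, names = FALSE)
  )
}

#' Pairwise correlation between two predictors' scores
#'
#' Pearson and Spearman correlations over pairwise-complete observations.
#'
#' @param data Variant tibble.
#' @param x,y Score columns (tidy evaluation).
#' @return One-row tibble: `pearson`, `pearson_p`, `spearman`,
#'   `spearman_p`, `n`.
#' @export
score_correlations <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  if (sum(ok) < 3) abort("need at least 3 complete score pairs")
  pe <- cor.test(xv[ok], yv[ok], method = "pearson")
  sp <- suppressWarnings(cor.test(xv[ok], yv[ok], method = "spearman",
                                  exact = FALSE))
  tibble::tibble(
    pearson = unname(pe$estimate), pearson_p = pe$p.value,
    spearman = unname(sp$estimate), spearman_p = sp$p.value,
    n = sum(ok)
  )
}

#' Harmonize three predictor scores and ternary-transform them
#'
#' Rescales the EVmutation, PoPMuSiC and SNAP2 scores of each variant to a
#' common deleteriousness scale (min-max on the observed range, EVmutation
#' negated so that higher always means more deleterious) and divides each
#' triple by its sum, yielding compositional coordinates that show the
#' predictors' relative contributions. An all-zero triple maps to the
#' barycenter (1/3, 1/3, 1/3). Rows missing any of the three scores are
#' dropped with a message.
#'
#' @param data Variant tibble.
#' @param ev,pop,snap Score columns (tidy evaluation); defaults
#'   `evmutation`, `popmusic_ddg`, `snap2`.
#' @param ranges Optional list with elements `ev`, `pop`, `snap`, each
#'   `c(min, max)`, overriding the observed rescaling ranges (recorded in
#'   the `ranges` attribute either way).
#' @return Complete-case rows of `data` with added `t_ev`, `t_pop`,
#'   `t_snap` (summing to 1); attribute `ranges` holds the ranges used.
#' @export
harmonize_ternary <- function(data, ev = evmutation, pop = popmusic_ddg,
                              snap = snap2, ranges = NULL) {
  evv <- dplyr::pull(data, {{ ev }})
  popv <- dplyr::pull(data, {{ pop }})
  snapv <- dplyr::pull(data, {{ snap }})
  ok <- is.finite(evv) & is.finite(popv) & is.finite(snapv)
  if (any(!ok)) {
    inform(sprintf("dropping %d row(s) missing one of the three scores",
                   sum(!ok)))
  }
  # orientation harmonization: higher = more deleterious
  h_ev <- -evv[ok]
  h_pop <- popv[ok]
  h_snap <- snapv[ok]
  used <- list(ev = ranges$ev %||% range(h_ev),
               pop = ranges$pop %||% range(h_pop),
               snap = ranges$snap %||% range(h_snap))
  if (any(vapply(used, function(r) diff(r) == 0, logical(1)))) {
    abort("degenerate score range: cannot rescale")
  }
  rescale <- function(x, r) (x - r[1]) / (r[2] - r[1])
  u <- cbind(rescale(h_ev, used$ev), rescale(h_pop, used$pop),
             rescale(h_snap, used$snap))
  s <- rowSums(u)
  t <- u / ifelse(s == 0, 1, s)
  t[s == 0, ] <- 1 / 3
  out <- data[ok, , drop = FALSE] |>
    dplyr::mutate(t_ev = t[, 1], t_pop = t[, 2], t_snap = t[, 3])
  attr(out, "ranges") <- used
  # note: ranges$ev is on the negated (deleteriousness) scale
  out
}

#' Two-dimensional region classification from EVmutation and SNAP2 scores
#'
#' Places each variant in one of three regions of the EVmutation x SNAP2
#' plane: putatively highly pathogenic (EVmutation < -7.5 and SNAP2 > 70),
#' putatively benign (EVmutation in [-4, -2] and SNAP2 < -50), or other.
#' Region boundaries are strict, so boundary values fall in `other`.
#'
#' @param ev,snap2 Numeric score vectors (recycled to common length).
#' @return Factor with levels `putatively_highly_pathogenic`,
#'   `putatively_benign`, `other`; `NA` when either score is missing.
#' @export
#' @examples
#' region_classify(c(-8, -3, -7.5), c(75, -60, 80))
region_classify <- function(ev, snap2) {
  n <- max(length(ev), length(snap2))
  ev <- rep_len(ev, n)
  snap2 <- rep_len(snap2, n)
  out <- dplyr::case_when(
    is.na(ev) | is.na(snap2) ~ NA_character_,
    ev < -7.5 & snap2 > 70 ~ "putatively_highly_pathogenic",
    ev >= -4 & ev <= -2 & snap2 < -50 ~ "putatively_benign",
    TRUE ~ "other"
  )
  factor(out, levels = c("putatively_highly_pathogenic", "putatively_benign",
                         "other"))
}
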