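# Alignment columns, conservation profiling and the GV/frequency correlation.

#' Read an aligned FASTA protein alignment
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a tidy
#' two-column tibble. Records must be equal length (gap character `-`).
#'
#' @param path Path to an aligned FASTA file.
#' @return Tibble with columns `id` (first word of the FASTA header) and
#'   `seq` (aligned sequence, uppercase).
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    id = vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1),
    seq = unname(toupper(as.character(aa)))
  )
}

#' Write an alignment tibble to aligned FASTA
#'
#' @param alignment Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  aa <- Biostrings::AAStringSet(setNames(alignment$seq, alignment$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Map an alignment onto reference residue positions
#'
#' Produces one row per non-gap position of the reference sequence, numbered
#' 1..L on the ungapped reference. Gap characters in the other sequences are
#' excluded from the observed residue multiset and counted in `n_gaps`.
#'
#' @param alignment Tibble with columns `id`, `seq` (equal-length aligned
#'   sequences, `-` for gaps), e.g. from [read_alignment()].
#' @param ref_id `id` of the reference sequence (default: first record).
#' @return Tibble with one row per reference position: `position`, `ref_aa`,
#'   `residues` (list-column of observed non-gap residues, reference
#'   included), `n_gaps`, `n_species` (number of non-gap residues), and
#'   `alignment_column` (1-based column index in the alignment).
#' @export
map_alignment <- function(alignment, ref_id = alignment$id[1]) {
  stopifnot(is.data.frame(alignment), all(c("id", "seq") %in% names(alignment)))
  lens <- nchar(alignment$seq)
  if (length(unique(lens)) != 1) {
    abort("ragged alignment: sequences have unequal aligned lengths")
  }
  if (!ref_id %in% alignment$id) {
    abort(sprintf("reference id %s not found in alignment", dQuote(ref_id, FALSE)))
  }
  chars <- do.call(rbind, strsplit(toupper(alignment$seq), ""))
  rownames(chars) <- alignment$id
  bad <- setdiff(unique(as.vector(chars)), c(AA_ALPHABET, "-"))
  if (length(bad) > 0) {
    abort(sprintf("non-standard alignment characters: %s",
                  paste(dQuote(bad, FALSE), collapse = ", ")))
  }
  ref_row <- chars[ref_id, ]
  keep <- which(ref_row != "-")
  cols <- lapply(keep, function(j) {
    col <- chars[, j]
    col[col != "-"]
  })
  tibble::tibble(
    position = seq_along(keep),
    ref_aa = unname(ref_row[keep]),
    residues = cols,
    n_gaps = nrow(chars) - lengths(cols),
    n_species = lengths(cols),
    alignment_column = keep
  )
}

#' Per-position conservation profile from alignment columns
#'
#' Scores each reference position with its Grantham variation and flags
#' invariant (single distinct residue) and conserved (`gv < gv_threshold`)
#' positions. Columns with fewer than two non-gap sequences cannot support a
#' range and are flagged unscorable (`scorable = FALSE`, `gv = NA`).
#'
#' @param columns Tibble from [map_alignment()].
#' @param gv_threshold Conservation cutoff in Grantham units; positions with
#'   GV strictly below it are called conserved. Default 61.3.
#' @param table Property table as returned by [grantham_table()].
#' @return `columns` with added `gv`, `invariant`, `conserved`, `scorable`.
#' @export
conservation_profile <- function(columns, gv_threshold = 61.3,
                                 table = grantham_table()) {
  stopifnot(is.data.frame(columns), "residues" %in% names(columns))
  scorable <- lengths(columns$residues) >= 2
  gvs <- ifelse(scorable,
                vapply(columns$residues, gv, numeric(1), table = table),
                NA_real_)
  out <- dplyr::mutate(
    columns,
    gv = gvs,
    scorable = scorable,
    invariant = vapply(.data$residues, function(r) length(unique(r)) == 1,
                       logical(1)),
    conserved = !is.na(gvs) & gvs < gv_threshold
  )
  attr(out, "gv_threshold") <- gv_threshold
  out
}

#' Correlation between conservation (GV) and mutation frequency
#'
#' Correlates per-position GV with the number of affected families reported
#' per residue, over all reference positions. Positions absent from
#' `family_counts` are counted as zero families; rank ties use midranks.
#'
#' @param profile Tibble from [conservation_profile()] (needs `position`,
#'   `gv`).
#' @param family_counts Either a numeric vector aligned with
#'   `profile$position`, or a data frame with columns `position`, `families`.
#' @return Tibble with one row per method (`pearson`, `spearman`):
#'   `estimate`, `p_value`, `n`.
#' @export
conservation_frequency_corr <- function(profile, family_counts) {
  stopifnot(is.data.frame(profile), all(c("position", "gv") %in% names(profile)))
  if (is.data.frame(family_counts)) {
    stopifnot(all(c("position", "families") %in% names(family_counts)))
    fam <- setNames(rep(0, nrow(profile)), profile$position)
    hit <- as.character(family_counts$position)
    fam[hit[hit %in% names(fam)]] <-
      family_counts$families[hit %in% names(fam)]
    fam <- unname(fam)
  } else {
    fam <- as.numeric(family_counts)
    if (length(fam) != nrow(profile)) {
      abort("family_counts length must equal the number of profile positions")
    }
  }
  ok <- !is.na(profile$gv) & !is.na(fam)
  g <- profile$gv[ok]
  f <- fam[ok]
  if (length(g) < 3) abort("need at least 3 scorable positions")
  if (sd(g) == 0 || sd(f) == 0) {
    abort("correlation undefined: constant GV or family-count vector")
  }
  pe <- cor.test(g, f, method = "pearson")
  sp <- suppressWarnings(cor.test(g, f, method = "spearman", exact = FALSE))
  tibble::tibble(
    method = c("pearson", "spearman"),
    estimate = c(unname(pe$estimate), unname(sp$estimate)),
    p_value = c(pe$p.value, sp$p.value),
    n = length(g)
  )
}

#' Write a conservation profile to TSV
#'
#' @param profile Tibble from [conservation_profile()].
#' @param path Output path.
#' @param comment Optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, comment = NULL) {
  flat <- dplyr::mutate(
    profile,
    residues_observed = vapply(.data$residues, paste, character(1),
                               collapse = ""),
    .keep = "unused"
  ) |>
    dplyr::select("position", "ref_aa", "residues_observed", "n_gaps",
                  "n_species", "gv", "invariant", "conserved", "scorable")
  header <- if (!is.null(comment)) paste0("# ", comment) else character(0)
  writeLines(c(header, sub("\n$", "", readr::format_tsv(flat))), path)
  invisible(path)
}
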