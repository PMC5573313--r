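# Grantham distance, Grantham variation (GV) and Grantham deviation (GD).

.check_residues <- function(x, arg = "residue") {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s code(s): %s", arg,
                  paste(dQuote(bad, FALSE), collapse = ", ")))
  }
  x
}

#' Grantham physicochemical distance between two amino acids
#'
#' Computes the unrounded Grantham (1974) distance
#' \eqn{D = \rho \sqrt{\alpha \Delta c^2 + \beta \Delta p^2 + \gamma \Delta v^2}}
#' between residues, in Grantham units. Vectorised over `a` and `b`.
#'
#' @param a,b Character vectors of single-letter residue codes (recycled).
#' @param table Property table as returned by [grantham_table()].
#' @return Numeric vector of non-negative distances; `D(a, a) = 0`.
#' @export
#' @examples
#' grantham_distance("T", "S")  # 57.75
#' grantham_distance("V", "I")  # 29.61
grantham_distance <- function(a, b, table = grantham_table()) {
  a <- .check_residues(a)
  b <- .check_residues(b)
  co <- attr(table, "coefficients") %||% grantham_coefficients()
  cv <- setNames(table$c, table$residue)
  pv <- setNames(table$p, table$residue)
  vv <- setNames(table$v, table$residue)
  co$rho * sqrt(co$alpha * (cv[a] - cv[b])^2 +
                co$beta  * (pv[a] - pv[b])^2 +
                co$gamma * (vv[a] - vv[b])^2) |> unname()
}

#' Full computed Grantham distance matrix
#'
#' @param table Property table as returned by [grantham_table()].
#' @return Symmetric 20 x 20 numeric matrix of unrounded distances.
#' @export
grantham_matrix <- function(table = grantham_table()) {
  res <- table$residue
  m <- outer(res, res, grantham_distance, table = table)
  dimnames(m) <- list(res, res)
  m
}

#' Grantham variation (GV) of an alignment column
#'
#' GV measures the physicochemical spread of the residues observed at one
#' alignment position: the Grantham-style distance between the componentwise
#' extremes of composition, polarity and volume over the observed residue
#' set. Invariant columns have GV = 0; a two-residue column reduces to the
#' pairwise [grantham_distance()]. Duplicate residues do not affect the value.
#'
#' @param residues Character vector of residue codes observed in the column
#'   (multiplicities allowed, ignored).
#' @param table Property table as returned by [grantham_table()].
#' @return Single non-negative GV value in Grantham units.
#' @export
#' @examples
#' gv(c("T", "S"))           # 57.75
#' gv(c("T", "T", "T"))      # 0
gv <- function(residues, table = grantham_table()) {
  if (length(residues) == 0) abort("empty residue set: GV is undefined")
  residues <- unique(.check_residues(residues))
  co <- attr(table, "coefficients") %||% grantham_coefficients()
  cv <- setNames(table$c, table$residue)[residues]
  pv <- setNames(table$p, table$residue)[residues]
  vv <- setNames(table$v, table$residue)[residues]
  co$rho * sqrt(co$alpha * diff(range(cv))^2 +
                co$beta  * diff(range(pv))^2 +
                co$gamma * diff(range(vv))^2)
}

#' Grantham deviation (GD) of a mutant residue from an alignment column
#'
#' GD measures how far a candidate (mutant) residue lies outside the
#' physicochemical ranges spanned by the residues observed at a position.
#' Each property deviation is the distance from the mutant's value to the
#' observed `[min, max]` interval (0 when inside); the deviations are then
#' combined with the Grantham formula. GD = 0 exactly when the mutant's
#' composition, polarity and volume all fall within the observed ranges; for
#' a single-residue column GD equals the pairwise distance.
#'
#' @param residues Character vector of residues observed in the column.
#' @param mutant Single residue code to evaluate.
#' @param table Property table as returned by [grantham_table()].
#' @return Single non-negative GD value in Grantham units.
#' @export
#' @examples
#' gd(c("T", "S"), "T")  # 0
#' gd("V", "I")          # 29.61
gd <- function(residues, mutant, table = grantham_table()) {
  if (length(residues) == 0) abort("empty residue set: GD is undefined")
  residues <- unique(.check_residues(residues))
  mutant <- .check_residues(mutant, "mutant")
  if (length(mutant) != 1) abort("`mutant` must be a single residue code")
  dev_from_range <- function(prop) {
    obs <- setNames(table[[prop]], table$residue)
    rng <- range(obs[residues])
    x <- obs[[mutant]]
    max(0, rng[1] - x, x - rng[2])
  }
  co <- attr(table, "coefficients") %||% grantham_coefficients()
  co$rho * sqrt(co$alpha * dev_from_range("c")^2 +
                co$beta  * dev_from_range("p")^2 +
                co$gamma * dev_from_range("v")^2)
}
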