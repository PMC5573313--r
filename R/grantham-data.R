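# Grantham (1974) amino-acid property values and coefficients.
#
# The physicochemical distance between two residues is
#   D(a, b) = rho * sqrt(alpha * dc^2 + beta * dp^2 + gamma * dv^2)
# with c = composition (atomic weight ratio of non-carbon side-chain atoms),
# p = polarity and v = side-chain volume (A^3). rho scales the mean distance
# over all pairs to 100.

.grantham_c <- c(A = 0,    R = 0.65, N = 1.33, D = 1.38, C = 2.75,
                 Q = 0.89, E = 0.92, G = 0.74, H = 0.58, I = 0,
                 L = 0,    K = 0.33, M = 0,    F = 0,    P = 0.39,
                 S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0)

.grantham_p <- c(A = 8.1,  R = 10.5, N = 11.6, D = 13.0, C = 5.5,
                 Q = 10.5, E = 12.3, G = 9.0,  H = 10.4, I = 5.2,
                 L = 4.9,  K = 11.3, M = 5.7,  F = 5.2,  P = 8.0,
                 S = 9.2,  T = 8.6,  W = 5.4,  Y = 6.2,  V = 5.9)

.grantham_v <- c(A = 31,   R = 124,  N = 56,   D = 54,   C = 55,
                 Q = 85,   E = 83,   G = 3,    H = 96,   I = 111,
                 L = 111,  K = 119,  M = 105,  F = 132,  P = 32.5,
                 S = 32,   T = 61,   W = 170,  Y = 136,  V = 84)

#' Grantham amino-acid property table
#'
#' The 1974 composition (`c`), polarity (`p`) and side-chain volume (`v`,
#' cubic angstroms) values for the 20 standard amino acids, together with the
#' coefficients used by [grantham_distance()].
#'
#' @return A tibble with columns `residue`, `c`, `p`, `v` and an attribute
#'   `coefficients` (list with `alpha`, `beta`, `gamma`, `rho`).
#' @seealso [grantham_distance()], [grantham_coefficients()]
#' @export
#' @examples
#' grantham_table()
grantham_table <- function() {
  res <- sort(names(.grantham_c))
  out <- tibble::tibble(
    residue = res,
    c = unname(.grantham_c[res]),
    p = unname(.grantham_p[res]),
    v = unname(.grantham_v[res])
  )
  attr(out, "coefficients") <- grantham_coefficients()
  out
}

#' Grantham distance coefficients
#'
#' Constants of the 1974 distance formula: property weights `alpha` (on
#' composition), `beta` (on polarity), `gamma` (on volume) and the overall
#' scale `rho` chosen so that the mean pairwise distance is 100.
#'
#' @return Named list with `alpha`, `beta`, `gamma`, `rho`.
#' @export
grantham_coefficients <- function() {
  list(alpha = 1.833, beta = 0.1018, gamma = 0.000399, rho = 50.723)
}

# Published integer Grantham distance matrix (1974), used as a fixed
# reference for the rounding cross-check in grantham_matrix() tests.
# Row/column order follows the original table: S R L P T A V G I F Y C H Q N
# K D E M W. The Asp-Trp entry is given as the formula-consistent 191; some
# printed copies of the table show 181 for this one pair.
.grantham_published_rows <- list(
  S = c(R = 110, L = 145, P = 74, T = 58, A = 99, V = 124, G = 56, I = 142,
        F = 155, Y = 144, C = 112, H = 89, Q = 68, N = 46, K = 121, D = 65,
        E = 80, M = 135, W = 177),
  R = c(L = 102, P = 103, T = 71, A = 112, V = 96, G = 125, I = 97, F = 97,
        Y = 77, C = 180, H = 29, Q = 43, N = 86, K = 26, D = 96, E = 54,
        M = 91, W = 101),
  L = c(P = 98, T = 92, A = 96, V = 32, G = 138, I = 5, F = 22, Y = 36,
        C = 198, H = 99, Q = 113, N = 153, K = 107, D = 172, E = 138,
        M = 15, W = 61),
  P = c(T = 38, A = 27, V = 68, G = 42, I = 95, F = 114, Y = 110, C = 169,
        H = 77, Q = 76, N = 91, K = 103, D = 108, E = 93, M = 87, W = 147),
  T = c(A = 58, V = 69, G = 59, I = 89, F = 103, Y = 92, C = 149, H = 47,
        Q = 42, N = 65, K = 78, D = 85, E = 65, M = 81, W = 128),
  A = c(V = 64, G = 60, I = 94, F = 113, Y = 112, C = 195, H = 86, Q = 91,
        N = 111, K = 106, D = 126, E = 107, M = 84, W = 148),
  V = c(G = 109, I = 29, F = 50, Y = 55, C = 192, H = 84, Q = 96, N = 133,
        K = 97, D = 152, E = 121, M = 21, W = 88),
  G = c(I = 135, F = 153, Y = 147, C = 159, H = 98, Q = 87, N = 80, K = 127,
        D = 94, E = 98, M = 127, W = 184),
  I = c(F = 21, Y = 33, C = 198, H = 94, Q = 109, N = 149, K = 102, D = 168,
        E = 134, M = 10, W = 61),
  F = c(Y = 22, C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
        E = 140, M = 28, W = 40),
  Y = c(C = 194, H = 83, Q = 99, N = 143, K = 85, D = 160, E = 122, M = 36,
        W = 37),
  C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170, M = 196,
        W = 215),
  H = c(Q = 24, N = 68, K = 32, D = 81, E = 40, M = 87, W = 115),
  Q = c(N = 46, K = 53, D = 61, E = 29, M = 101, W = 130),
  N = c(K = 94, D = 23, E = 42, M = 142, W = 174),
  K = c(D = 101, E = 56, M = 95, W = 110),
  D = c(E = 45, M = 160, W = 191),
  E = c(M = 126, W = 152),
  M = c(W = 67)
)

#' Published integer Grantham distance matrix
#'
#' The symmetric 20 x 20 integer distance matrix as published in 1974,
#' embedded as a fixed reference. Computed unrounded distances from
#' [grantham_distance()] round to these values within +/- 1. The Asp-Trp
#' entry is the formula-consistent 191; printed copies of the table vary for
#' this one pair.
#'
#' @return Symmetric integer matrix with dimnames over the 20 standard
#'   residues (alphabetical) and zero diagonal.
#' @export
grantham_published <- function() {
  m <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (a in names(.grantham_published_rows)) {
    row <- .grantham_published_rows[[a]]
    for (b in names(row)) {
      m[a, b] <- m[b, a] <- as.integer(row[[b]])
    }
  }
  m
}
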