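# Shared residue-level constants and small helpers.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

# Reduced 7-class residue alphabet used by the statistical potentials:
# hydrophobic, aromatic, polar, positive, negative, glycine, proline.
AA_CLASS <- c(
  A = 1L, V = 1L, L = 1L, I = 1L, M = 1L, C = 1L,
  F = 2L, W = 2L, Y = 2L, H = 2L,
  S = 3L, T = 3L, N = 3L, Q = 3L, X = 3L,
  K = 4L, R = 4L,
  D = 5L, E = 5L,
  G = 6L,
  P = 7L
)

ATOM_NAMES <- c("N", "CA", "C", "O", "CB")

seq_to_vec <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  toupper(sequence)
}

check_sequence <- function(aa) {
  bad <- setdiff(unique(aa), c(AA1, "X"))
  if (length(bad))
    stop("sequence contains non-standard residue(s): ",
         paste(bad, collapse = ", "))
  invisible(aa)
}

aa_class <- function(aa) unname(AA_CLASS[seq_to_vec(aa)])

wrap_angle <- function(x) {
  x <- (x + 180) %% 360
  x - 180
}

#' Dihedral angle of four points
#'
#' IUPAC-signed torsion a-b-c-d in degrees.
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
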