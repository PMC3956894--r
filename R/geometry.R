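# Torsion-space chain building and structural comparison metrics.

#' Conformation objects
#'
#' A conformation holds one protein chain: its sequence, per-residue backbone
#' torsions (phi, psi, omega in degrees) and the derived backbone + Cbeta
#' coordinates. Coordinates are an `L x 5 x 3` array over atoms
#' N, CA, C, O, CB; glycine carries a virtual CB (contact distances fall back
#' to CA for glycine, see [contact_coords()]).
#'
#' @param sequence One-letter amino-acid string (or character vector).
#' @param torsions `L x 3` matrix of (phi, psi, omega) in degrees. `omega`
#'   defaults to 180 (trans) when a two-column matrix is given.
#' @return An object of class `conformation`.
#' @examples
#' helix <- build_chain(strrep("A", 12), cbind(-57, -47)[rep(1, 12), ])
#' ca <- ca_coords(helix)
#' sqrt(sum((ca[2, ] - ca[1, ])^2))  # ~3.8 A
#' @export
build_chain <- function(sequence, torsions) {
  aa <- check_sequence(seq_to_vec(sequence))
  L <- length(aa)
  torsions <- as.matrix(torsions)
  if (ncol(torsions) == 2L) torsions <- cbind(torsions, 180)
  if (nrow(torsions) != L || ncol(torsions) != 3L)
    stop("torsions must be an L x 3 (or L x 2) matrix matching the sequence")
  torsions <- wrap_angle(torsions)
  colnames(torsions) <- c("phi", "psi", "omega")
  flat <- .cpp_build_chain(torsions[, 1], torsions[, 2], torsions[, 3])
  xyz <- aperm(array(t(flat), dim = c(3, 5, L)), c(3, 2, 1))
  dimnames(xyz) <- list(NULL, ATOM_NAMES, c("x", "y", "z"))
  new_conformation(aa, torsions, xyz)
}

new_conformation <- function(aa, torsions, xyz, segments = NULL) {
  structure(list(
    sequence = paste(aa, collapse = ""),
    aa = aa,
    torsions = torsions,
    xyz = xyz,
    segments = segments %||% rep(1L, length(aa))
  ), class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", length(x$aa), " residues\n", sep = "")
  cat("  sequence: ",
      if (nchar(x$sequence) > 50) paste0(substr(x$sequence, 1, 50), "...")
      else x$sequence, "\n", sep = "")
  invisible(x)
}

#' Number of residues of a conformation
#' @param conf A `conformation`.
#' @return Integer length.
#' @export
n_res <- function(conf) length(conf$aa)

#' CA coordinates of a conformation
#' @param conf A `conformation`.
#' @return `L x 3` matrix.
#' @export
ca_coords <- function(conf) conf$xyz[, "CA", , drop = TRUE]

#' Contact-bearing coordinates (CB, CA for glycine)
#'
#' Contact distances throughout the package are measured between CB atoms,
#' falling back to CA for glycine.
#'
#' @param conf A `conformation`.
#' @return `L x 3` matrix.
#' @export
contact_coords <- function(conf) {
  cb <- conf$xyz[, "CB", , drop = TRUE]
  gly <- conf$aa == "G"
  if (any(gly)) cb[gly, ] <- conf$xyz[gly, "CA", , drop = FALSE]
  cb
}

#' Extract backbone torsions from coordinates
#'
#' Inverse of [build_chain()]: phi, psi, omega (degrees) computed from the
#' N/CA/C coordinates. phi of the first residue and psi/omega entries that
#' need a neighbouring residue are returned as stored if the conformation was
#' built from torsions, otherwise NA at chain termini.
#'
#' @param conf A `conformation`.
#' @return `L x 3` matrix of (phi, psi, omega) in degrees.
#' @export
extract_torsions <- function(conf) {
  L <- n_res(conf)
  x <- conf$xyz
  out <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(L)) {
    if (i > 1)
      out[i, 1] <- dihedral(x[i - 1, "C", ], x[i, "N", ], x[i, "CA", ],
                            x[i, "C", ])
    if (i < L) {
      out[i, 2] <- dihedral(x[i, "N", ], x[i, "CA", ], x[i, "C", ],
                            x[i + 1, "N", ])
      out[i + 1, 3] <- dihedral(x[i, "CA", ], x[i, "C", ], x[i + 1, "N", ],
                                x[i + 1, "CA", ])
    }
  }
  out
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `a` onto `b` using a proper
#' rotation only.
#'
#' @param a,b `n x 3` coordinate matrices (or conformations, in which case CA
#'   traces are used), `n >= 3`.
#' @return A list of class `superposition` with elements `rotation` (3x3,
#'   det +1), `translation` (length-3) and `rmsd`, such that
#'   `a %*% rotation + translation` best fits `b`.
#' @export
superpose <- function(a, b) {
  a <- as_points(a); b <- as_points(b)
  if (nrow(a) != nrow(b)) stop("point sets must have equal size")
  if (nrow(a) < 3) stop("need at least 3 points")
  if (degenerate_points(a) || degenerate_points(b))
    stop("degenerate (collinear) point set")
  fit <- .cpp_kabsch(a, b)
  structure(list(rotation = fit$rotation,
                 translation = drop(fit$translation),
                 rmsd = fit$rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

as_points <- function(x) {
  if (inherits(x, "conformation")) return(ca_coords(x))
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("expected an n x 3 coordinate matrix")
  storage.mode(m) <- "double"
  m
}

degenerate_points <- function(m) {
  cm <- sweep(m, 2, colMeans(m))
  qr(cm)$rank < 2
}

#' Apply a superposition to coordinates
#' @param sp A `superposition`.
#' @param x `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(sp, x) {
  sweep(as_points(x) %*% sp$rotation, 2, -sp$translation)
}

#' TM-score d0 length scale
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, clamped to at least 0.5 A for short
#' chains.
#'
#' @param l_ref Reference length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref) {
  if (l_ref <= 15) return(0.5)
  max(0.5, 1.24 * (l_ref - 15)^(1 / 3) - 1.8)
}

#' TM-score between two equal-length CA traces
#'
#' Length-normalized structural similarity in (0, 1], normalized by the
#' reference length. The superposition maximizing the score is searched
#' deterministically: seed superpositions from all contiguous windows at
#' several window lengths, each refined by iterative distance-cutoff residue
#' reselection, with a final score-weighted polish.
#'
#' @param model,reference Conformations or `L x 3` CA matrices of equal
#'   length (`L >= 3`).
#' @param d0 Optional override of the length scale (default [tm_d0()] of the
#'   reference length).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference, d0 = NULL) {
  x <- as_points(model); y <- as_points(reference)
  if (nrow(x) != nrow(y)) stop("model and reference must have equal length")
  if (nrow(y) < 3) stop("reference too short for TM-score (L < 3)")
  d0 <- d0 %||% tm_d0(nrow(y))
  .cpp_tm_score(x, y, d0)
}

#' Distance-matrix error (DME)
#'
#' Superposition-free root-mean-square difference of intramolecular CA-CA
#' distances over all residue pairs i < j.
#'
#' @param a,b Conformations or `L x 3` CA matrices of equal length.
#' @return DME in Angstrom.
#' @export
dme <- function(a, b) {
  x <- as_points(a); y <- as_points(b)
  if (nrow(x) != nrow(y)) stop("length mismatch")
  da <- dist(x); db <- dist(y)
  sqrt(mean((da - db)^2))
}

#' Radius of gyration of the CA trace
#' @param conf A `conformation` or `n x 3` matrix.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  m <- as_points(conf)
  cm <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2, cm)^2)))
}

#' Backbone-geometry secondary-structure state
#'
#' Classifies each residue as H (helix), E (strand) or C (coil) from its
#' (phi, psi) torsions; used both for fragment annotation and the
#' hydrogen-bond/secondary-structure reward term.
#'
#' @param torsions `L x 2+` matrix with phi and psi in the first two columns,
#'   or a `conformation`.
#' @return Character vector of states in `c("H", "E", "C")`.
#' @export
ss_from_torsions <- function(torsions) {
  if (inherits(torsions, "conformation")) torsions <- torsions$torsions
  phi <- wrap_angle(torsions[, 1]); psi <- wrap_angle(torsions[, 2])
  st <- rep("C", length(phi))
  st[phi > -120 & phi < -30 & psi > -80 & psi < -5] <- "H"
  st[phi >= -180 & phi < -90 & (psi > 90 | psi < -150)] <- "E"
  st[is.na(phi) | is.na(psi)] <- "C"
  st
}
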