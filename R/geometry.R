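# Core numerical geometry: torsions, chi-1, Kabsch superposition,
# minimal heavy-atom distances.

#' Torsion angle of four points
#'
#' IUPAC sign convention: cis = 0 degrees, range (-180, 180], positive
#' for a clockwise rotation of the far bond viewed down the central bond.
#' Invariant under reversal of the atom order (a torsion reads the same
#' from either end of the chain).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-9) stop("undefined dihedral: central bond has zero length")
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("undefined dihedral: three consecutive points are collinear")
  cross_n <- c(n1[2] * n2[3] - n1[3] * n2[2],
               n1[3] * n2[1] - n1[1] * n2[3],
               n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(cross_n * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  # fold exact -180 onto +180 so the range is (-180, 180]
  if (isTRUE(all.equal(ang, -180))) ang <- 180
  ang
}

# Gamma heavy atom defining chi-1 per residue type.
.CHI1_GAMMA <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", GLN = "CG", GLU = "CG", HIS = "CG",
  LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG", PRO = "CG", TRP = "CG",
  TYR = "CG", ALY = "CG", MLY = "CG", MSE = "CG",
  ILE = "CG1", VAL = "CG1", THR = "OG1", SER = "OG", CYS = "SG"
)

#' Sidechain chi-1 angle of a residue
#'
#' chi-1 is the N-CA-CB-gamma torsion; the gamma heavy atom depends on
#' residue type (CG for Glu, CG1 for Val/Ile, OG1 for Thr, ...).  For a
#' residue modelled in alternate conformations, pass `altloc`; atoms with
#' a blank altloc are shared between conformers.
#'
#' @param res Atom table of a single residue.
#' @param altloc Alternate-location id, or `""` (default) for the
#'   single-conformer case.
#' @return chi-1 in degrees.
#' @seealso [chi1_altlocs()] for all conformers at once.
#' @export
chi1 <- function(res, altloc = "") {
  rn <- unique(res$resname)
  if (length(rn) != 1) stop("chi1 expects atoms of a single residue")
  gamma <- .CHI1_GAMMA[rn]
  if (is.na(gamma))
    stop("chi-1 undefined for residue type ", rn)
  pick <- function(name) {
    hit <- res[res$atom == name & res$alt %in% c("", altloc), , drop = FALSE]
    if (nrow(hit) == 0)
      stop("chi-1 undefined: missing atom ", name,
           if (altloc != "") paste0(" (altloc '", altloc, "')"))
    # prefer the requested conformer over the shared copy
    hit <- hit[order(hit$alt != altloc), , drop = FALSE]
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  dihedral(pick("N"), pick("CA"), pick("CB"), pick(gamma))
}

#' chi-1 of every alternate conformer of a residue
#'
#' @param res Atom table of a single residue.
#' @return Named numeric vector of chi-1 angles, one per altloc present
#'   (a single unnamed value when the residue has no altlocs).
#' @export
chi1_altlocs <- function(res) {
  alts <- sort(setdiff(unique(res$alt), ""))
  if (length(alts) == 0) return(chi1(res, ""))
  vapply(stats::setNames(alts, alts), function(a) chi1(res, a), numeric(1))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (weighted)
#' RMSD mapping point set `P` onto `Q`, by SVD of the cross-covariance
#' with determinant correction so reflections are never returned.
#'
#' @param P,Q Numeric n x 3 matrices, n >= 3, matched rows.
#' @param weights Optional non-negative weights (default uniform).
#' @return A `bd_transform`: list with `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` over the fitted points; apply with
#'   [apply_transform()].
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stop("superposition error: point sets must be matched n x 3 matrices")
  n <- nrow(P)
  if (n < 3) stop("superposition error: need at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) <= 0)
    stop("superposition error: invalid weights")
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    stop("superposition error: degenerate (collinear) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.vector(R %*% cp)
  fit <- Pc %*% t(R) - Qc
  rmsd <- sqrt(sum(w * rowSums(fit^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "bd_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param X n x 3 coordinate matrix.
#' @param tr A `bd_transform` from [kabsch()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(X, tr) {
  sweep(as.matrix(X) %*% t(tr$rotation), 2, tr$translation, "+")
}

# Apply a transform to a whole structure (atoms and waters).
transform_structure <- function(struct, tr) {
  for (tab in c("atom", "water")) {
    if (nrow(struct[[tab]]) == 0) next
    xyz <- apply_transform(coord_matrix(struct[[tab]]), tr)
    struct[[tab]]$x <- xyz[, 1]
    struct[[tab]]$y <- xyz[, 2]
    struct[[tab]]$z <- xyz[, 3]
  }
  struct
}

#' Minimal heavy-atom distance between two residues
#'
#' Minimum over all heavy-atom pairs across all altloc combinations
#' (a contact made by any modelled conformer counts).  Ties break
#' deterministically by atom-name order.
#'
#' @param res_a,res_b Atom tables of the two residues.
#' @return List with `distance` (Angstrom), `atom_a`, `atom_b`, `alt_a`,
#'   `alt_b`.
#' @export
min_heavy_atom_distance <- function(res_a, res_b) {
  a <- res_a[!res_a$hydrogen, , drop = FALSE]
  b <- res_b[!res_b$hydrogen, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("no heavy atoms in one of the residues")
  D <- cross_dist(coord_matrix(a), coord_matrix(b))
  ij <- which(D == min(D), arr.ind = TRUE)
  ord <- order(a$atom[ij[, 1]], b$atom[ij[, 2]])
  i <- ij[ord[1], 1]; j <- ij[ord[1], 2]
  list(distance = D[i, j],
       atom_a = a$atom[i], atom_b = b$atom[j],
       alt_a = a$alt[i], alt_b = b$alt[j])
}
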