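# Independent oracles used to cross-check the package implementations.
# Each is deliberately written with a different algorithm than the
# package uses.

# Horn's closed-form quaternion superposition: returns the optimal rmsd
# mapping P onto Q (proper rotations only), via the eigen-decomposition
# of the 4x4 quaternion matrix -- independent of the SVD route.
quaternion_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- t(Pc) %*% Qc
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# Signed torsion by an independent construction: project the outer
# bonds onto the plane perpendicular to the central bond and measure
# the signed angle via the scalar triple product.
torsion_by_projection <- function(p1, p2, p3, p4) {
  u <- (p3 - p2); u <- u / sqrt(sum(u^2))
  a <- (p1 - p2) - sum((p1 - p2) * u) * u
  b <- (p4 - p3) - sum((p4 - p3) * u) * u
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  triple <- sum(u * c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                      a[1]*b[2]-a[2]*b[1]))
  if (triple < 0) -ang else ang
}

# Exhaustive double loop over heavy-atom pairs.
brute_min_distance <- function(res_a, res_b) {
  a <- res_a[!res_a$hydrogen, ]
  b <- res_b[!res_b$hydrogen, ]
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt((a$x[i]-b$x[j])^2 + (a$y[i]-b$y[j])^2 + (a$z[i]-b$z[j])^2)
    if (d < best) best <- d
  }
  best
}

# Full three-matrix affine-gap Needleman-Wunsch score (Gotoh),
# penalties as pairwiseAlignment: opening a gap of length k costs
# gap_open + k * gap_ext.
nw_affine_score <- function(s1, s2, submat, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- submat[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i-1, j-1], X[i-1, j-1], Y[i-1, j-1]) + sc
    X[i, j] <- max(M[i-1, j] - gap_open - gap_ext, X[i-1, j] - gap_ext)
    Y[i, j] <- max(M[i, j-1] - gap_open - gap_ext, Y[i, j-1] - gap_ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Closed-form JSD of a gap-free invariant column against a background.
jsd_point_mass <- function(aa, bg) {
  p <- stats::setNames(rep(0, length(bg)), names(bg))
  p[aa] <- 1
  m <- (p + bg) / 2
  kl <- function(x, y) { nz <- x > 0; sum(x[nz] * log2(x[nz] / y[nz])) }
  0.5 * kl(p, m) + 0.5 * kl(bg, m)
}

# Second implementation of greedy maxmin selection (index bookkeeping
# done differently), same tie-break rule: input order.
maxmin_oracle <- function(D, n) {
  N <- nrow(D)
  best_val <- -1; best_pair <- NULL
  for (i in 1:(N - 1)) for (j in (i + 1):N)
    if (D[i, j] > best_val) { best_val <- D[i, j]; best_pair <- c(i, j) }
  sel <- best_pair
  while (length(sel) < n) {
    cand_best <- -1; cand_idx <- NA
    for (k in seq_len(N)) {
      if (k %in% sel) next
      mk <- min(D[k, sel])
      if (mk > cand_best) { cand_best <- mk; cand_idx <- k }
    }
    sel <- c(sel, cand_idx)
  }
  sort(sel)
}

# Minimal hand-built residue: atom table rows at given coordinates.
toy_residue <- function(chain, resno, resname, atoms, xyz, alt = NULL,
                        occ = NULL, element = NULL) {
  k <- length(atoms)
  data.frame(record = "ATOM", chain = chain, resno = as.integer(resno),
             ins = "", resname = resname, atom = atoms,
             alt = if (is.null(alt)) rep("", k) else alt,
             element = if (is.null(element)) substr(atoms, 1, 1) else element,
             occ = if (is.null(occ)) rep(1, k) else occ, b = 0,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             hydrogen = FALSE, stringsAsFactors = FALSE)
}

# Rotate xyz about an axis by angle (degrees); for fixture building.
rot_about_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

blosum <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Deposited coordinate files (not distributed): tests of the published
# complex look here.
deposited_path <- function(entry) {
  dir <- system.file("extdata", "deposited", package = "bromospec")
  file.path(dir, paste0(entry, ".pdb"))
}
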