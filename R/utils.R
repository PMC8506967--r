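# Shared lookups and small helpers.

# Water residue names recognised in coordinate files.
.WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# Backbone heavy atoms of an amino-acid residue (OXT closes the C-terminus).
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Mapping from modified residue codes to their parent one-letter code
#'
#' Post-translationally modified residues are polymer residues here and map
#' to the parent amino acid for sequence work (acetyl-lysine reads as K).
#' The table is exported so pipelines with unusual chemistry can extend it
#' via the `mod_map` argument of [polymer_sequence()].
#'
#' @format Named character vector: three-letter code -> one-letter code.
#' @export
MODIFIED_RESIDUE_MAP <- c(
  ALY = "K", MLY = "K", M3L = "K", KCX = "K",
  SEP = "S", TPO = "T", PTR = "Y",
  CSO = "C", CME = "C", OCS = "C",
  MSE = "M", HYP = "P", PCA = "Q"
)

.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# BLOSUM62 amino-acid background frequencies (Henikoff marginals),
# renormalised to sum to one.  Order follows .AA1.
.BLOSUM62_BACKGROUND <- local({
  f <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  f / sum(f)
})

.pkg_cache <- new.env(parent = emptyenv())

# BLOSUM62 substitution matrix (from Biostrings), cached.
blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

# BLOSUM62-positive neighbours of residue `aa` (excluding `aa` itself).
similar_residues <- function(aa) {
  m <- blosum62()
  hits <- .AA1[m[aa, .AA1] > 0]
  setdiff(hits, aa)
}

# One-letter code for a three-letter residue name; "X" with warning when
# unknown.  `mod_map` supplies parent codes for modified residues.
aa_one <- function(resname, mod_map = MODIFIED_RESIDUE_MAP) {
  resname <- toupper(resname)
  out <- character(length(resname))
  std <- suppressWarnings(bio3d::aa321(resname))
  out[] <- std
  mod <- resname %in% names(mod_map)
  out[mod] <- unname(mod_map[resname[mod]])
  bad <- is.na(out) | !(out %in% .AA1)
  if (any(bad)) {
    warning("unknown residue code(s) mapped to 'X': ",
            paste(unique(resname[bad]), collapse = ", "))
    out[bad] <- "X"
  }
  out
}

# Residue key used to split atom tables into residues.
res_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

# Euclidean cross-distance matrix between two coordinate matrices (n x 3).
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

coord_matrix <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}
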