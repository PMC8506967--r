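# Sequence-guided pairing of homologous domains and iterative pruned
# Kabsch superposition with per-residue deviation profiles.

#' Parameters for pairing and pruned superposition
#'
#' `prune_cutoff` (2.0 A default) is the post-fit C-alpha deviation above
#' which a residue pair is discarded between fitting rounds; pruning is
#' batch-wise (all offending pairs drop each round) and monotone (a
#' pruned pair never returns), so the iteration reaches a fixed point.
#'
#' @param prune_cutoff Angstrom.
#' @param max_iterations Iteration cap.
#' @param min_retained_pairs Fewer retained pairs aborts with an error.
#' @param gap_opening,gap_extension Affine gap penalties for the global
#'   sequence alignment seeding the pairing.
#' @param submat Substitution matrix name (a Biostrings data set).
#' @return A `bd_superpose_params` list.
#' @export
superpose_params <- function(prune_cutoff = 2.0, max_iterations = 50,
                             min_retained_pairs = 3,
                             gap_opening = 10, gap_extension = 0.5,
                             submat = "BLOSUM62") {
  if (prune_cutoff <= 0) stop("prune_cutoff must be positive")
  structure(list(prune_cutoff = prune_cutoff,
                 max_iterations = max_iterations,
                 min_retained_pairs = min_retained_pairs,
                 gap_opening = gap_opening,
                 gap_extension = gap_extension,
                 submat = submat),
            class = "bd_superpose_params")
}

# C-alpha coordinates per residue: blank altloc preferred, else the
# highest-occupancy conformer (ties by altloc letter).
ca_table <- function(atoms) {
  ca <- atoms[atoms$atom == "CA" & !atoms$hydrogen, , drop = FALSE]
  if (nrow(ca) == 0) return(ca)
  ca <- ca[order(ca$resno, ca$ins, ca$alt != "", -ca$occ, ca$alt), ,
           drop = FALSE]
  ca <- ca[!duplicated(res_key(ca)), , drop = FALSE]
  rownames(ca) <- NULL
  ca
}

#' Pair residues of two domains by global sequence alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps, via
#' Biostrings) of the two C-alpha-bearing sequences; every aligned
#' non-gap column yields one residue pair.  A warning is raised when the
#' alignment score is negative (effectively unrelated sequences).
#'
#' @param ref_atoms,mobile_atoms Atom tables (e.g. [select_residues()]).
#' @param params [superpose_params()].
#' @return Data frame `bd_pairing`: `ref_resno`, `ref_ins`, `ref_aa`,
#'   `mobile_resno`, `mobile_ins`, `mobile_aa`, ordered by reference
#'   author number.
#' @export
pair_by_sequence <- function(ref_atoms, mobile_atoms,
                             params = superpose_params()) {
  rs <- polymer_sequence(ref_atoms)
  ms <- polymer_sequence(mobile_atoms)
  if (nchar(rs$sequence) < 10 || nchar(ms$sequence) < 10)
    stop("sequences too short to pair (need >= 10 residues)")
  mat <- blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rs$sequence), Biostrings::AAString(ms$sequence),
    substitutionMatrix = mat, gapOpening = params$gap_opening,
    gapExtension = params$gap_extension, type = "global")
  if (Biostrings::score(aln) < 0)
    warning("alignment score below zero: sequences may be unrelated")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ri <- cumsum(pa != "-")
  mi <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  out <- data.frame(ref_resno = rs$resno[ri[both]],
                    ref_ins = rs$ins[ri[both]],
                    ref_aa = pa[both],
                    mobile_resno = ms$resno[mi[both]],
                    mobile_ins = ms$ins[mi[both]],
                    mobile_aa = sa[both],
                    stringsAsFactors = FALSE)
  class(out) <- c("bd_pairing", class(out))
  out
}

#' Iterative pruned C-alpha superposition
#'
#' Fits the mobile domain onto the reference over the paired C-alpha
#' atoms, then repeatedly discards pairs whose post-fit deviation
#' exceeds `prune_cutoff` and refits, until the retained set is stable
#' (or `max_iterations`).  The deviation profile under the final
#' transform is reported for every pair, pruned or not, so flexible
#' loops remain visible.
#'
#' @param ref_atoms,mobile_atoms Atom tables of the two domains.
#' @param pairing From [pair_by_sequence()] (computed when `NULL`).
#' @param params [superpose_params()].
#' @return A `bd_superposition`: `transform` (mobile -> reference),
#'   `rmsd_retained`, `n_retained`, `n_total`, `profile` (per-pair data
#'   frame with `deviation`, `retained`, `identity_match`), `iterations`.
#' @export
iterative_prune_superpose <- function(ref_atoms, mobile_atoms,
                                      pairing = NULL,
                                      params = superpose_params()) {
  if (is.null(pairing)) pairing <- pair_by_sequence(ref_atoms, mobile_atoms, params)
  if (nrow(pairing) < params$min_retained_pairs)
    stop("superposition divergence: fewer than ", params$min_retained_pairs,
         " pairs to start from")
  rca <- ca_table(ref_atoms)
  mca <- ca_table(mobile_atoms)
  rk <- match(paste(pairing$ref_resno, pairing$ref_ins),
              paste(rca$resno, rca$ins))
  mk <- match(paste(pairing$mobile_resno, pairing$mobile_ins),
              paste(mca$resno, mca$ins))
  ok <- !is.na(rk) & !is.na(mk)
  pairing <- pairing[ok, , drop = FALSE]
  Q <- coord_matrix(rca[rk[ok], ])      # reference
  P <- coord_matrix(mca[mk[ok], ])      # mobile
  n <- nrow(pairing)
  retained <- rep(TRUE, n)
  tr <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    tr <- kabsch(P[retained, , drop = FALSE], Q[retained, , drop = FALSE])
    dev <- sqrt(rowSums((apply_transform(P, tr) - Q)^2))
    keep <- retained & dev <= params$prune_cutoff
    if (sum(keep) < params$min_retained_pairs)
      stop("superposition divergence: retained pairs fell below ",
           params$min_retained_pairs)
    if (identical(keep, retained) || iter >= params$max_iterations) {
      retained <- keep
      break
    }
    retained <- keep
  }
  tr_final <- kabsch(P[retained, , drop = FALSE],
                     Q[retained, , drop = FALSE])
  dev <- sqrt(rowSums((apply_transform(P, tr_final) - Q)^2))
  profile <- cbind(pairing,
                   data.frame(deviation = dev, retained = retained,
                              identity_match = pairing$ref_aa == pairing$mobile_aa,
                              stringsAsFactors = FALSE))
  rownames(profile) <- NULL
  structure(list(transform = tr_final,
                 rmsd_retained = tr_final$rmsd,
                 n_retained = sum(retained),
                 n_total = n,
                 profile = profile,
                 iterations = iter),
            class = "bd_superposition")
}

#' @export
print.bd_superposition <- function(x, ...) {
  cat(sprintf("<bd_superposition> rmsd %.3f A over %d of %d Ca pairs (%d iterations)\n",
              x$rmsd_retained, x$n_retained, x$n_total, x$iterations))
  invisible(x)
}

#' Deviations of contact residues after superposition
#'
#' Extracts, in reference numbering, the post-fit C-alpha deviation of
#' each contact residue, flagging residues whose counterpart in the
#' mobile structure has a different amino-acid identity and reporting
#' unpaired contact residues as missing rather than zero.
#'
#' @param result A `bd_superposition`.
#' @param contact_resnos Integer vector of reference author numbers.
#' @return Data frame: `ref_resno`, `ref_aa`, `mobile_resno`,
#'   `mobile_aa`, `deviation`, `retained`, `identity_match`, `status`
#'   (`"paired"` or `"unpaired"`); attributes `max_dev` and `mean_dev`
#'   over the paired residues.
#' @export
contact_deviation_summary <- function(result, contact_resnos) {
  pr <- result$profile
  idx <- match(contact_resnos, pr$ref_resno)
  out <- data.frame(
    ref_resno = contact_resnos,
    ref_aa = ifelse(is.na(idx), NA_character_, pr$ref_aa[idx]),
    mobile_resno = ifelse(is.na(idx), NA_integer_, pr$mobile_resno[idx]),
    mobile_aa = ifelse(is.na(idx), NA_character_, pr$mobile_aa[idx]),
    deviation = ifelse(is.na(idx), NA_real_, pr$deviation[idx]),
    retained = ifelse(is.na(idx), NA, pr$retained[idx]),
    identity_match = ifelse(is.na(idx), NA, pr$identity_match[idx]),
    status = ifelse(is.na(idx), "unpaired", "paired"),
    stringsAsFactors = FALSE)
  attr(out, "max_dev") <- suppressWarnings(max(out$deviation, na.rm = TRUE))
  attr(out, "mean_dev") <- mean(out$deviation, na.rm = TRUE)
  out
}

#' Superpose two bound peptides over a residue range
#'
#' Direct Kabsch fit (no pruning) of peptide C-alpha atoms matched by
#' author residue number over an inclusive range; used to ask whether
#' two bound histone tails adopt the same conformation.
#'
#' @param ref_struct,mobile_struct `bd_structure`s.
#' @param ref_sel,mobile_sel Peptide-chain [selection()]s.
#' @param range Length-2 inclusive author-number range, e.g. `c(13, 17)`.
#' @return List with `rmsd` and the `transform`.
#' @export
superpose_peptides <- function(ref_struct, mobile_struct,
                               ref_sel, mobile_sel, range) {
  stopifnot(length(range) == 2)
  want <- seq(range[1], range[2])
  get_ca <- function(struct, sel, label) {
    ca <- ca_table(select_residues(struct, sel))
    ca <- ca[ca$resno %in% want, , drop = FALSE]
    missing <- setdiff(want, ca$resno)
    if (length(missing) > 0)
      stop(label, " peptide is missing C-alpha for residue(s) ",
           paste(missing, collapse = ", "))
    ca[order(ca$resno), , drop = FALSE]
  }
  rca <- get_ca(ref_struct, ref_sel, "reference")
  mca <- get_ca(mobile_struct, mobile_sel, "mobile")
  tr <- kabsch(coord_matrix(mca), coord_matrix(rca))
  list(rmsd = tr$rmsd, transform = tr)
}
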