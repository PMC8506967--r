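# Contact-residue identification: direct heavy-atom contacts at a
# distance cutoff and single-water hydrogen-bond bridges between a
# reader domain and its bound peptide.

#' Parameters for contact calling
#'
#' `direct_cutoff` is the heavy-atom distance defining a direct contact
#' (3.0 A default, the conventional "touching" criterion for
#' domain-peptide interfaces).  `hbond_cutoff` bounds both legs of a
#' water-mediated hydrogen bond (3.5 A default, the conventional
#' heavy-atom donor/acceptor limit); the bridge criterion is
#' distance-only, with no angular term and no explicit hydrogens.
#'
#' @param direct_cutoff Angstrom, direct-contact limit.
#' @param hbond_cutoff Angstrom, per-leg water-bridge limit.
#' @param include_sulfur Count S among polar (hydrogen-bonding) elements.
#' @return A `bd_contact_params` list.
#' @export
contact_params <- function(direct_cutoff = 3.0, hbond_cutoff = 3.5,
                           include_sulfur = FALSE) {
  if (!(direct_cutoff > 0 && direct_cutoff <= hbond_cutoff &&
        hbond_cutoff <= 5.0))
    stop("require 0 < direct_cutoff <= hbond_cutoff <= 5.0")
  structure(list(direct_cutoff = direct_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 polar_elements = c("N", "O", if (include_sulfur) "S")),
            class = "bd_contact_params")
}

# Empty contact record table (shared schema for direct + bridge records).
empty_contacts <- function() {
  data.frame(bd_chain = character(0), bd_resno = integer(0),
             bd_ins = character(0), bd_resname = character(0),
             pep_chain = character(0), pep_resno = integer(0),
             pep_ins = character(0), pep_resname = character(0),
             kind = character(0), distance = numeric(0),
             distance2 = numeric(0), bd_atom = character(0),
             pep_atom = character(0), water_resno = integer(0),
             bd_side = character(0), stringsAsFactors = FALSE)
}

bd_side_of <- function(atom) {
  ifelse(atom %in% .BACKBONE_ATOMS, "backbone", "sidechain")
}

check_selections <- function(bd_sel, pep_sel) {
  if (bd_sel$chain == pep_sel$chain) {
    lo_a <- if (is.null(bd_sel$from)) -Inf else bd_sel$from
    hi_a <- if (is.null(bd_sel$to)) Inf else bd_sel$to
    lo_b <- if (is.null(pep_sel$from)) -Inf else pep_sel$from
    hi_b <- if (is.null(pep_sel$to)) Inf else pep_sel$to
    if (lo_a <= hi_b && lo_b <= hi_a)
      stop("domain and peptide selections overlap")
  }
  invisible(TRUE)
}

#' Direct heavy-atom contacts between domain and peptide
#'
#' One record per (domain residue, peptide residue) pair with any
#' heavy-atom distance at or below `direct_cutoff`, annotated with the
#' closest atom pair.  All heavy atoms count (hydrophobic packing
#' contacts are contacts); hydrogens and waters are excluded; alternate
#' conformers all participate, so a contact made by any conformer is
#' reported.
#'
#' @param struct A `bd_structure`.
#' @param bd_sel,pep_sel [selection()]s for the domain and peptide;
#'   must not overlap.
#' @param params [contact_params()].
#' @return Contact record data frame (kind `"direct"`).
#' @export
find_direct_contacts <- function(struct, bd_sel, pep_sel,
                                 params = contact_params()) {
  check_selections(bd_sel, pep_sel)
  bd <- select_residues(struct, bd_sel)
  pep <- select_residues(struct, pep_sel)
  bd <- bd[!bd$hydrogen, , drop = FALSE]
  pep <- pep[!pep$hydrogen, , drop = FALSE]
  if (nrow(bd) == 0 || nrow(pep) == 0)
    stop("empty domain or peptide selection")
  D <- cross_dist(coord_matrix(bd), coord_matrix(pep))
  hit <- which(D <= params$direct_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_contacts())
  key <- paste(res_key(bd)[hit[, 1]], res_key(pep)[hit[, 2]], sep = "~")
  # per residue pair keep the minimal-distance atom pair (ties by name)
  ord <- order(key, D[hit], bd$atom[hit[, 1]], pep$atom[hit[, 2]])
  hit <- hit[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  i <- hit[keep, 1]; j <- hit[keep, 2]
  out <- data.frame(
    bd_chain = bd$chain[i], bd_resno = bd$resno[i], bd_ins = bd$ins[i],
    bd_resname = bd$resname[i],
    pep_chain = pep$chain[j], pep_resno = pep$resno[j],
    pep_ins = pep$ins[j], pep_resname = pep$resname[j],
    kind = "direct", distance = D[cbind(i, j)], distance2 = NA_real_,
    bd_atom = bd$atom[i], pep_atom = pep$atom[j],
    water_resno = NA_integer_, bd_side = bd_side_of(bd$atom[i]),
    stringsAsFactors = FALSE)
  out <- out[order(out$bd_resno, out$bd_ins, out$pep_resno, out$pep_ins), ]
  rownames(out) <- NULL
  out
}

#' Water-mediated hydrogen-bond bridges between domain and peptide
#'
#' A bridge is a single water whose oxygen lies within `hbond_cutoff` of
#' at least one polar (N/O) domain atom and at least one polar peptide
#' atom.  One record is emitted per (water, domain residue, peptide
#' residue) combination, with both legs reported (domain leg in
#' `distance`, peptide leg in `distance2`).  No waters means no bridges,
#' not an error.
#'
#' @inheritParams find_direct_contacts
#' @return Contact record data frame (kind `"water_bridge"`).
#' @export
find_water_bridges <- function(struct, bd_sel, pep_sel,
                               params = contact_params()) {
  check_selections(bd_sel, pep_sel)
  wat <- struct$water[struct$water$element == "O", , drop = FALSE]
  if (nrow(wat) == 0) return(empty_contacts())
  polar <- function(a)
    a[!a$hydrogen & a$element %in% params$polar_elements, , drop = FALSE]
  bd <- polar(select_residues(struct, bd_sel))
  pep <- polar(select_residues(struct, pep_sel))
  if (nrow(bd) == 0 || nrow(pep) == 0) return(empty_contacts())
  Dw_bd <- cross_dist(coord_matrix(wat), coord_matrix(bd))
  Dw_pep <- cross_dist(coord_matrix(wat), coord_matrix(pep))
  res <- list()
  for (w in seq_len(nrow(wat))) {
    bi <- which(Dw_bd[w, ] <= params$hbond_cutoff)
    pj <- which(Dw_pep[w, ] <= params$hbond_cutoff)
    if (length(bi) == 0 || length(pj) == 0) next
    # minimal-leg atom per residue on each side
    for (bk in split(bi, res_key(bd)[bi])) {
      b <- bk[order(Dw_bd[w, bk], bd$atom[bk])][1]
      for (pk in split(pj, res_key(pep)[pj])) {
        p <- pk[order(Dw_pep[w, pk], pep$atom[pk])][1]
        res[[length(res) + 1]] <- data.frame(
          bd_chain = bd$chain[b], bd_resno = bd$resno[b],
          bd_ins = bd$ins[b], bd_resname = bd$resname[b],
          pep_chain = pep$chain[p], pep_resno = pep$resno[p],
          pep_ins = pep$ins[p], pep_resname = pep$resname[p],
          kind = "water_bridge",
          distance = Dw_bd[w, b], distance2 = Dw_pep[w, p],
          bd_atom = bd$atom[b], pep_atom = pep$atom[p],
          water_resno = wat$resno[w], bd_side = bd_side_of(bd$atom[b]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) return(empty_contacts())
  out <- do.call(rbind, res)
  out <- out[order(out$bd_resno, out$pep_resno, out$water_resno), ]
  rownames(out) <- NULL
  out
}

#' Union of contacting domain residues
#'
#' Deduplicated domain residues from direct and water-bridge records,
#' ordered by author number and tagged with the contributing contact
#' kinds and sides.
#'
#' @param direct,bridges Contact record data frames.
#' @return Data frame: one row per contacting domain residue with
#'   `kinds` (comma-joined) and `bd_sides`.
#' @export
contact_residue_set <- function(direct, bridges = empty_contacts()) {
  rec <- rbind(direct, bridges)
  if (nrow(rec) == 0)
    return(data.frame(bd_chain = character(0), bd_resno = integer(0),
                      bd_ins = character(0), bd_resname = character(0),
                      kinds = character(0), bd_sides = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(rec$bd_chain, rec$bd_resno, rec$bd_ins, sep = "|")
  agg <- lapply(split(seq_len(nrow(rec)), key), function(idx) {
    r <- rec[idx[1], c("bd_chain", "bd_resno", "bd_ins", "bd_resname")]
    r$kinds <- paste(sort(unique(rec$kind[idx])), collapse = ",")
    r$bd_sides <- paste(sort(unique(rec$bd_side[idx])), collapse = ",")
    r
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$bd_resno, out$bd_ins), ]
  rownames(out) <- NULL
  out
}

#' Peptide footprint: which domain residues touch each peptide residue
#'
#' @param direct,bridges Contact record data frames.
#' @return Long data frame with one row per unique (peptide residue,
#'   domain residue) pair and the contact kinds linking them.
#' @export
peptide_footprint <- function(direct, bridges = empty_contacts()) {
  rec <- rbind(direct, bridges)
  if (nrow(rec) == 0)
    return(data.frame(pep_resno = integer(0), pep_resname = character(0),
                      bd_resno = integer(0), bd_resname = character(0),
                      kinds = character(0), stringsAsFactors = FALSE))
  key <- paste(rec$pep_resno, rec$pep_ins, rec$bd_resno, rec$bd_ins)
  agg <- lapply(split(seq_len(nrow(rec)), key), function(idx) {
    data.frame(pep_resno = rec$pep_resno[idx[1]],
               pep_resname = rec$pep_resname[idx[1]],
               bd_resno = rec$bd_resno[idx[1]],
               bd_resname = rec$bd_resname[idx[1]],
               kinds = paste(sort(unique(rec$kind[idx])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$pep_resno, out$bd_resno), ]
  rownames(out) <- NULL
  out
}
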