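# Synthetic-data generators with recorded ground truth: toy
# domain-peptide complexes with planted contacts and water bridges,
# perturbed structure families with known rigid transforms and
# displaced segments, and ortholog-style alignments with planted
# conservation structure.  Every generator is a pure function of its
# spec (including the seed): repeated calls are identical.

.AA3_NOGLY <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","HIS","ILE",
                "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

# Heavy-atom offsets from CA for a sparse but correctly named residue.
.RES_OFFSETS <- rbind(
  N  = c(-1.2,  0.8, 0.0),
  CA = c( 0.0,  0.0, 0.0),
  C  = c( 1.2,  0.8, 0.0),
  O  = c( 1.4,  1.9, 0.3),
  CB = c( 0.0, -1.5, 0.6)
)

atom_rows <- function(chain, resno, resname, ca, record = "ATOM",
                      flip = FALSE) {
  off <- .RES_OFFSETS
  if (flip) off[, 2] <- -off[, 2]
  data.frame(record = record, chain = chain, resno = as.integer(resno),
             ins = "", resname = resname,
             atom = rownames(off), alt = "",
             element = substr(rownames(off), 1, 1),
             occ = 1, b = 20,
             x = ca[1] + off[, 1], y = ca[2] + off[, 2],
             z = ca[3] + off[, 3],
             hydrogen = FALSE, stringsAsFactors = FALSE)
}

water_row <- function(resno, pos) {
  data.frame(record = "HETATM", chain = "W", resno = as.integer(resno),
             ins = "", resname = "HOH", atom = "O", alt = "",
             element = "O", occ = 1, b = 30,
             x = pos[1], y = pos[2], z = pos[3],
             hydrogen = FALSE, stringsAsFactors = FALSE)
}

#' Specification of a synthetic domain-peptide complex
#'
#' Planted interactions are built to exact distances; every other
#' inter-chain residue pair is kept well clear of the contact cutoffs,
#' and decoy waters respect an exclusion shell around all atoms, so the
#' generated ground truth is the complete contact list.
#'
#' @param n_domain,n_peptide Residue counts (domain chain A numbered
#'   from 1201, peptide chain B from 11).
#' @param direct_contacts Data frame `bd`, `pep` (1-based residue
#'   indices) and `dist` (target minimal heavy-atom distance, Angstrom).
#' @param water_bridges Data frame `bd`, `pep`, `d1` (water-domain leg),
#'   `d2` (water-peptide leg).
#' @param n_decoy_waters Waters placed at least `exclusion` from
#'   everything.
#' @param exclusion Decoy exclusion shell, Angstrom (> hbond cutoff).
#' @param seed Integer seed.
#' @return A `bd_complex_spec` list.
#' @export
complex_spec <- function(n_domain = 20, n_peptide = 5,
                         direct_contacts = data.frame(
                           bd = c(3, 8), pep = c(1, 3),
                           dist = c(2.8, 2.6)),
                         water_bridges = data.frame(
                           bd = 14, pep = 5, d1 = 2.8, d2 = 2.8),
                         n_decoy_waters = 8, exclusion = 4.5, seed = 1) {
  stopifnot(exclusion > 3.5,
            all(direct_contacts$dist > 0),
            all(direct_contacts$pep <= n_peptide),
            all(direct_contacts$bd <= n_domain))
  used <- c(direct_contacts$pep, if (nrow(water_bridges)) water_bridges$pep)
  if (anyDuplicated(used))
    stop("each peptide residue may carry at most one planted interaction")
  structure(list(n_domain = n_domain, n_peptide = n_peptide,
                 direct_contacts = direct_contacts,
                 water_bridges = water_bridges,
                 n_decoy_waters = n_decoy_waters,
                 exclusion = exclusion, seed = as.integer(seed)),
            class = "bd_complex_spec")
}

#' Generate a synthetic domain-peptide complex with known contacts
#'
#' @param spec A [complex_spec()].
#' @return List: `structure` (a `bd_structure`), `bd_sel`, `pep_sel`
#'   ([selection()]s), `truth_direct`, `truth_bridges` (planted
#'   interactions in author numbering).
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "bd_complex_spec"))
  withr::with_seed(spec$seed, make_complex_impl(spec))
}

make_complex_impl <- function(spec) {
  bd_nums <- 1200L + seq_len(spec$n_domain)
  pep_nums <- 10L + seq_len(spec$n_peptide)
  bd_names <- sample(.AA3_NOGLY, spec$n_domain, replace = TRUE)
  pep_names <- sample(.AA3_NOGLY, spec$n_peptide, replace = TRUE)
  # gentle deterministic wiggle keeps the CA trace non-collinear
  dom_ca <- function(i) c(6 * i, 0.4 * sin(i), 0.4 * cos(2 * i))
  dom <- do.call(rbind, lapply(seq_len(spec$n_domain), function(i)
    atom_rows("A", bd_nums[i], bd_names[i], dom_ca(i))))
  # peptide parked 30 A away; planted residues are relocated below
  pep_ca <- lapply(seq_len(spec$n_peptide), function(j) c(6 * j, 30, 0))
  pep_flip <- rep(FALSE, spec$n_peptide)
  dc <- spec$direct_contacts
  for (k in seq_len(nrow(dc))) {
    i <- dc$bd[k]; j <- dc$pep[k]
    # peptide CB sits exactly dist below the domain residue's CB
    bd_cb <- dom_ca(i) + c(0, -1.5, 0.6)
    pep_cb_target <- bd_cb + c(0, -dc$dist[k], 0)
    # flipped residue: CB points up (+1.5 y), so CA = CB - (0, 1.5, 0.6)
    pep_ca[[j]] <- pep_cb_target - c(0, 1.5, 0.6)
    pep_flip[j] <- TRUE
  }
  wb <- spec$water_bridges
  waters <- list()
  wno <- 500L
  if (!is.null(wb) && nrow(wb) > 0) for (k in seq_len(nrow(wb))) {
    i <- wb$bd[k]; j <- wb$pep[k]
    a <- dom_ca(i) + c(1.4, 1.9, 0.3)        # domain residue O
    L <- wb$d1[k] + wb$d2[k]                 # collinear bridge geometry
    b <- a + c(0, L, 0)                      # peptide residue N target
    # flipped residue: sidechain points away from the domain
    pep_ca[[j]] <- b + c(1.2, 0.8, 0)        # flipped N = CA + (-1.2, -0.8, 0)
    pep_flip[j] <- TRUE
    wno <- wno + 1L
    waters[[length(waters) + 1]] <- water_row(wno, a + c(0, wb$d1[k], 0))
  }
  pep <- do.call(rbind, lapply(seq_len(spec$n_peptide), function(j)
    atom_rows("B", pep_nums[j], pep_names[j], pep_ca[[j]],
              flip = pep_flip[j])))
  atom <- rbind(dom, pep)
  planted_w <- if (length(waters)) do.call(rbind, waters) else
    water_row(0, c(0, 0, 0))[0, ]
  # decoy waters: rejection-sampled outside the exclusion shell
  all_xyz <- rbind(coord_matrix(atom), coord_matrix(planted_w))
  decoys <- list()
  for (d in seq_len(spec$n_decoy_waters)) {
    placed <- FALSE
    for (try in 1:1000) {
      pos <- c(stats::runif(1, -10, 6 * spec$n_domain + 10),
               stats::runif(1, -25, 45), stats::runif(1, -20, 20))
      if (min(cross_dist(matrix(pos, 1), all_xyz)) >= spec$exclusion) {
        wno <- wno + 1L
        decoys[[length(decoys) + 1]] <- water_row(wno, pos)
        all_xyz <- rbind(all_xyz, pos)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("generation error: could not place decoy water")
  }
  water <- rbind(planted_w,
                 if (length(decoys)) do.call(rbind, decoys))
  st <- new_structure("synthetic_complex", atom, water)
  truth_direct <- data.frame(bd_resno = bd_nums[dc$bd],
                             pep_resno = pep_nums[dc$pep],
                             dist = dc$dist, stringsAsFactors = FALSE)
  truth_bridges <- if (!is.null(wb) && nrow(wb) > 0)
    data.frame(bd_resno = bd_nums[wb$bd], pep_resno = pep_nums[wb$pep],
               d1 = wb$d1, d2 = wb$d2, stringsAsFactors = FALSE)
  else data.frame(bd_resno = integer(0), pep_resno = integer(0),
                  d1 = numeric(0), d2 = numeric(0))
  verify_complex(st, truth_direct, truth_bridges)
  list(structure = st,
       bd_sel = selection("A"), pep_sel = selection("B"),
       truth_direct = truth_direct, truth_bridges = truth_bridges)
}

# Planted distances must be exact; unplanned residue pairs and water
# legs must keep a >= 0.2 A margin from the default cutoffs.
verify_complex <- function(st, truth_direct, truth_bridges,
                           margin = 0.2) {
  p <- contact_params()
  scan <- p$direct_cutoff + margin
  direct <- find_direct_contacts(st, selection("A"), selection("B"),
                                 contact_params(direct_cutoff = scan,
                                                hbond_cutoff = 5))
  want <- paste(truth_direct$bd_resno, truth_direct$pep_resno)
  reachable <- truth_direct$dist <= scan + 1e-9
  got <- paste(direct$bd_resno, direct$pep_resno)
  if (!setequal(got, want[reachable]))
    stop("generation error: unplanned near-cutoff direct contact")
  m <- match(want[reachable], got)
  if (any(abs(direct$distance[m] - truth_direct$dist[reachable]) > 0.05))
    stop("generation error: planted direct distance off target")
  hscan <- p$hbond_cutoff + margin
  bridges <- find_water_bridges(st, selection("A"), selection("B"),
                                contact_params(hbond_cutoff = hscan))
  reachb <- truth_bridges$d1 <= hscan & truth_bridges$d2 <= hscan
  wantb <- paste(truth_bridges$bd_resno, truth_bridges$pep_resno)
  gotb <- paste(bridges$bd_resno, bridges$pep_resno)
  if (!setequal(gotb, wantb[reachb]))
    stop("generation error: unplanned or missing water bridge")
  mb <- match(wantb[reachb], gotb)
  if (any(abs(bridges$distance[mb] - truth_bridges$d1[reachb]) > 0.05) ||
      any(abs(bridges$distance2[mb] - truth_bridges$d2[reachb]) > 0.05))
    stop("generation error: planted bridge legs off target")
  invisible(TRUE)
}

#' Specification of a synthetic structure family
#'
#' @param n_residues Residues in the base domain (helical C-alpha trace
#'   with N/CA/C/O/CB atoms).
#' @param n_members Number of perturbed copies.
#' @param noise_sd Per-coordinate Gaussian noise, Angstrom.
#' @param displaced_range Inclusive residue-index range rigidly shifted
#'   by `displacement` (NULL for none).
#' @param displacement 3-vector, Angstrom.
#' @param n_mutations Random residue-identity changes per member.
#' @param seed Integer seed.
#' @return A `bd_family_spec` list.
#' @export
family_spec <- function(n_residues = 100, n_members = 5, noise_sd = 0.3,
                        displaced_range = c(81, 100),
                        displacement = c(5, 0, 0), n_mutations = 0,
                        seed = 1) {
  stopifnot(noise_sd >= 0,
            is.null(displaced_range) ||
              (displaced_range[1] >= 1 && displaced_range[2] <= n_residues))
  structure(list(n_residues = n_residues, n_members = n_members,
                 noise_sd = noise_sd, displaced_range = displaced_range,
                 displacement = displacement, n_mutations = n_mutations,
                 seed = as.integer(seed)),
            class = "bd_family_spec")
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

build_domain <- function(n_residues, resnames, auth_start = 1L) {
  # compact four-helix bundle: globular like a real reader domain, so
  # rigid-body recovery is well conditioned in every direction
  per <- ceiling(n_residues / 4)
  idx <- seq_len(n_residues) - 1L
  seg <- idx %/% per          # helix 0..3
  j <- idx %% per             # position within helix
  theta <- j * 100 * pi / 180
  updown <- ifelse(seg %% 2 == 0, 1, -1)
  z0 <- ifelse(seg %% 2 == 0, 0, 1.5 * per)
  ca <- cbind(11 * seg + 2.3 * cos(theta),
              2.3 * sin(theta),
              z0 + updown * 1.5 * j)
  atom <- do.call(rbind, lapply(seq_len(n_residues), function(i)
    atom_rows("A", auth_start + i - 1L, resnames[i], ca[i, ])))
  new_structure("synthetic_domain", atom, water_row(0, c(0, 0, 0))[0, ])
}

#' Generate a perturbed structure family with recorded transforms
#'
#' Each member is the base domain plus coordinate noise, an optional
#' rigidly displaced segment, optional residue-identity mutations, and
#' a recorded random rigid transform.  Superposing a member back onto
#' the base should recover the inverse transform and prune the
#' displaced segment.
#'
#' @param spec A [family_spec()].
#' @return List: `base` (a `bd_structure`), `members` (list of
#'   `bd_structure`), `transforms` (applied rotation/translation per
#'   member, with the inverse that superposition should recover),
#'   `mutations` (per member), `displaced_resnos`.
#' @export
make_family <- function(spec) {
  stopifnot(inherits(spec, "bd_family_spec"))
  withr::with_seed(spec$seed, make_family_impl(spec))
}

make_family_impl <- function(spec) {
  resnames <- sample(.AA3_NOGLY, spec$n_residues, replace = TRUE)
  base <- build_domain(spec$n_residues, resnames)
  displaced <- if (is.null(spec$displaced_range)) integer(0) else
    seq(spec$displaced_range[1], spec$displaced_range[2])
  members <- list(); transforms <- list(); mutations <- list()
  for (m in seq_len(spec$n_members)) {
    st <- base
    st$id <- paste0("member_", m)
    mut <- data.frame(resno = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE)
    if (spec$n_mutations > 0) {
      pos <- sample(spec$n_residues, spec$n_mutations)
      for (p in pos) {
        old <- resnames[p]
        new <- sample(setdiff(.AA3_NOGLY, old), 1)
        st$atom$resname[st$atom$resno == p] <- new
        mut <- rbind(mut, data.frame(resno = p, from = old, to = new,
                                     stringsAsFactors = FALSE))
      }
    }
    n_at <- nrow(st$atom)
    if (spec$noise_sd > 0) {
      st$atom$x <- st$atom$x + stats::rnorm(n_at, 0, spec$noise_sd)
      st$atom$y <- st$atom$y + stats::rnorm(n_at, 0, spec$noise_sd)
      st$atom$z <- st$atom$z + stats::rnorm(n_at, 0, spec$noise_sd)
    }
    if (length(displaced) > 0) {
      sel <- st$atom$resno %in% displaced
      st$atom$x[sel] <- st$atom$x[sel] + spec$displacement[1]
      st$atom$y[sel] <- st$atom$y[sel] + spec$displacement[2]
      st$atom$z[sel] <- st$atom$z[sel] + spec$displacement[3]
    }
    R <- random_rotation()
    tv <- stats::runif(3, -20, 20)
    tr <- structure(list(rotation = R, translation = tv, rmsd = NA_real_),
                    class = "bd_transform")
    st <- transform_structure(st, tr)
    members[[m]] <- st
    transforms[[m]] <- list(
      rotation = R, translation = tv,
      inverse_rotation = t(R),
      inverse_translation = as.vector(-t(R) %*% tv))
    mutations[[m]] <- mut
  }
  list(base = base, members = members, transforms = transforms,
       mutations = mutations, displaced_resnos = displaced)
}

#' Specification of a synthetic ortholog alignment
#'
#' Column classes: `invariant` columns carry the master residue in every
#' row; `conservative` columns substitute only within the BLOSUM62 > 0
#' neighbour set of the master residue, at `conservative_rate`;
#' `random` columns substitute uniformly over the 20 amino acids at
#' `random_rate`.  Gaps are introduced per cell (never in the reference
#' row) at `gap_rate`, with optional per-column overrides.
#'
#' @param n_rows,n_cols Alignment dimensions.
#' @param n_invariant,n_conservative Planted conserved columns (placed
#'   deterministically from the seed); the rest are `random`.
#' @param conservative_rate,random_rate Per-cell substitution rates.
#' @param gap_rate Per-cell gap probability (non-reference rows).
#' @param gap_cols Optional named vector: column index -> gap rate
#'   override.
#' @param master Optional master sequence (length `n_cols`).
#' @param seed Integer seed.
#' @return A `bd_msa_spec` list.
#' @export
msa_spec <- function(n_rows = 100, n_cols = 110,
                     n_invariant = max(1, round(n_cols * 15 / 110)),
                     n_conservative = max(1, round(n_cols * 15 / 110)),
                     conservative_rate = 0.05,
                     random_rate = 0.20, gap_rate = 0.02,
                     gap_cols = NULL, master = NULL, seed = 1) {
  stopifnot(n_invariant + n_conservative <= n_cols,
            conservative_rate >= 0, conservative_rate <= 1,
            random_rate >= 0, random_rate <= 1,
            gap_rate >= 0, gap_rate <= 1)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 n_invariant = n_invariant,
                 n_conservative = n_conservative,
                 conservative_rate = conservative_rate,
                 random_rate = random_rate, gap_rate = gap_rate,
                 gap_cols = gap_cols, master = master,
                 seed = as.integer(seed)),
            class = "bd_msa_spec")
}

#' Generate a synthetic ortholog alignment with planted conservation
#'
#' @param spec An [msa_spec()].
#' @return List: `msa` (a `bd_msa`, reference row `ref`), `classes`
#'   (per-column class), `conserved_cols` (planted conserved column
#'   indices: invariant + conservative).
#' @export
make_msa <- function(spec) {
  stopifnot(inherits(spec, "bd_msa_spec"))
  withr::with_seed(spec$seed, make_msa_impl(spec))
}

make_msa_impl <- function(spec) {
  nc <- spec$n_cols; nr <- spec$n_rows
  master <- if (is.null(spec$master))
    sample(.AA1, nc, replace = TRUE) else strsplit(spec$master, "")[[1]]
  stopifnot(length(master) == nc)
  cons_cols <- sample(nc, spec$n_invariant + spec$n_conservative)
  classes <- rep("random", nc)
  classes[cons_cols[seq_len(spec$n_invariant)]] <- "invariant"
  if (spec$n_conservative > 0)
    classes[cons_cols[spec$n_invariant + seq_len(spec$n_conservative)]] <-
      "conservative"
  M <- matrix(rep(master, each = nr), nrow = nr)
  for (j in seq_len(nc)) {
    others <- 2:nr
    if (classes[j] == "conservative") {
      sim <- similar_residues(master[j])
      if (length(sim) > 0) {
        sub <- others[stats::runif(nr - 1) < spec$conservative_rate]
        M[sub, j] <- sample(sim, length(sub), replace = TRUE)
      }
    } else if (classes[j] == "random") {
      sub <- others[stats::runif(nr - 1) < spec$random_rate]
      M[sub, j] <- sample(.AA1, length(sub), replace = TRUE)
    }
    g <- spec$gap_rate
    if (!is.null(spec$gap_cols) && as.character(j) %in% names(spec$gap_cols))
      g <- spec$gap_cols[[as.character(j)]]
    if (g > 0) {
      gp <- others[stats::runif(nr - 1) < g]
      M[gp, j] <- "-"
    }
  }
  ids <- c("ref", sprintf("ortho%03d", seq_len(nr - 1)))
  out <- msa(apply(M, 1, paste, collapse = ""), ids = ids, ref_id = "ref")
  list(msa = out, classes = classes,
       conserved_cols = sort(cons_cols))
}
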