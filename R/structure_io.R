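# Reading PDB/mmCIF coordinate files into a uniform structure model.
#
# Parsing is delegated to bio3d (read.pdb / read.cif); this module
# normalises the result into a single atom table with author numbering,
# altloc and occupancy preserved, waters split out, hydrogens flagged.

#' Load a macromolecular structure from a PDB or mmCIF file
#'
#' Reads the first model of a coordinate file into a `bd_structure`: a
#' list with an `atom` table (all non-water atoms, one row per atom,
#' alternate locations retained, hydrogens flagged), a `water` table
#' (every water residue), and the structure `id`.  Author residue
#' numbering (`resno` plus insertion code `ins`) is the coordinate
#' system used throughout the package, matching how structural papers
#' refer to residues.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"cif"`.
#' @return A `bd_structure` object.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' s0 <- make_complex(complex_spec(seed = 1))$structure
#' write_pdb(s0, pdb)
#' s <- load_structure(pdb)
#' nrow(s$atom)
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (format == "pdb") {
    n_models <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
    if (n_models > 1)
      warning("multi-model file: first model used (", n_models, " models)")
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       rm.insert = FALSE, verbose = FALSE)),
      error = function(e) stop("PDB parse error in '", path, "': ",
                               conditionMessage(e)))
  } else {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                       rm.insert = FALSE, verbose = FALSE)),
      error = function(e) stop("mmCIF parse error in '", path, "': ",
                               conditionMessage(e)))
  }
  at <- pdb$atom
  blank <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  }
  element <- blank(at$elesy)
  guess <- element == ""
  if (any(guess)) element[guess] <- guess_element(at$elety[guess])
  atoms <- data.frame(
    record = as.character(at$type),
    chain = blank(at$chain),
    resno = as.integer(at$resno),
    ins = blank(at$insert),
    resname = toupper(as.character(at$resid)),
    atom = as.character(at$elety),
    alt = blank(at$alt),
    element = toupper(element),
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atoms$hydrogen <- atoms$element %in% c("H", "D")
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in '", path, "'")
  is_water <- atoms$resname %in% .WATER_NAMES
  new_structure(id = sub("\\.[^.]*$", "", basename(path)),
                atom = atoms[!is_water, , drop = FALSE],
                water = atoms[is_water, , drop = FALSE])
}

new_structure <- function(id, atom, water) {
  rownames(atom) <- NULL
  rownames(water) <- NULL
  structure(list(id = id, atom = atom, water = water, model_index = 1L),
            class = "bd_structure")
}

guess_element <- function(name) {
  n <- gsub("[^A-Za-z]", "", name)
  two <- toupper(n) %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA",
                           "CU", "NI", "CO", "SE", "CD", "HG")
  # atom names starting with a digit-stripped H are hydrogens (1HB etc.)
  out <- toupper(substr(n, 1, 1))
  out[two & nchar(n) >= 2] <- toupper(substr(n[two & nchar(n) >= 2], 1, 2))
  out
}

#' @export
print.bd_structure <- function(x, ...) {
  ch <- unique(x$atom$chain)
  cat("<bd_structure> ", x$id, ": ", nrow(x$atom), " atoms, ",
      length(unique(res_key(x$atom))), " residues in chain(s) ",
      paste(ch, collapse = ","), "; ",
      length(unique(res_key(x$water))), " waters\n", sep = "")
  invisible(x)
}

#' Chain/residue-range selection
#'
#' @param chain Chain identifier.
#' @param from,to Optional inclusive author residue-number range.
#' @return A `bd_selection` list.
#' @export
selection <- function(chain, from = NULL, to = NULL) {
  if (!is.null(from) && !is.null(to) && from > to)
    stop("selection range lo > hi: ", from, " > ", to)
  structure(list(chain = as.character(chain),
                 from = from, to = to), class = "bd_selection")
}

#' Select residues of a structure by chain and residue range
#'
#' @param struct A `bd_structure`.
#' @param sel A [selection()].
#' @return Atom table (data frame) of the selected residues, ordered by
#'   author residue number; zero rows when the range matches nothing.
#' @export
select_residues <- function(struct, sel) {
  stopifnot(inherits(struct, "bd_structure"), inherits(sel, "bd_selection"))
  chains <- unique(struct$atom$chain)
  if (!sel$chain %in% chains)
    stop("unknown chain '", sel$chain, "'; available: ",
         paste(chains, collapse = ", "))
  a <- struct$atom[struct$atom$chain == sel$chain, , drop = FALSE]
  if (!is.null(sel$from)) a <- a[a$resno >= sel$from, , drop = FALSE]
  if (!is.null(sel$to))   a <- a[a$resno <= sel$to, , drop = FALSE]
  a <- a[order(a$resno, a$ins), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' One-letter sequence of a residue selection
#'
#' Residues must share a chain; only residues bearing a C-alpha atom
#' enter the sequence (ions and caps are excluded with a warning).
#' Modified residues map to their parent code via `mod_map`.
#'
#' @param atoms Atom table, e.g. from [select_residues()].
#' @param mod_map Modified-residue mapping, default [MODIFIED_RESIDUE_MAP].
#' @return List with `sequence` (string), `resno` and `ins` vectors giving
#'   the author number of every sequence position.
#' @export
polymer_sequence <- function(atoms, mod_map = MODIFIED_RESIDUE_MAP) {
  if (nrow(atoms) == 0)
    return(list(sequence = "", resno = integer(0), ins = character(0)))
  if (length(unique(atoms$chain)) > 1)
    stop("residues span multiple chains: ",
         paste(unique(atoms$chain), collapse = ", "))
  keys <- res_key(atoms)
  uk <- unique(keys)
  has_ca <- vapply(uk, function(k)
    any(atoms$atom[keys == k] == "CA"), logical(1))
  if (any(!has_ca))
    warning(sum(!has_ca), " residue(s) without C-alpha excluded")
  uk <- uk[has_ca]
  first <- match(uk, keys)
  letters1 <- aa_one(atoms$resname[first], mod_map)
  list(sequence = paste(letters1, collapse = ""),
       resno = atoms$resno[first],
       ins = atoms$ins[first])
}

#' Count polymer residues and waters
#'
#' @param struct A `bd_structure`.
#' @return List with `n_polymer` (non-water residues across all chains)
#'   and `n_water`.
#' @export
count_residues <- function(struct) {
  list(n_polymer = length(unique(res_key(struct$atom))),
       n_water = length(unique(res_key(struct$water))))
}

#' Write a structure to a PDB file
#'
#' Minimal fixed-width writer used for fixtures and synthetic data;
#' preserves altlocs, occupancies and author numbering so that a
#' write/read round trip is lossless for the fields this package uses.
#'
#' @param struct A `bd_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(struct, path) {
  at <- rbind(struct$atom, struct$water)
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    nm <- at$atom[i]
    nm4 <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    lines[i] <- sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$record[i], i %% 100000L, nm4, at$alt[i], at$resname[i],
      at$chain[i], at$resno[i],
      ifelse(at$ins[i] == "", " ", at$ins[i]),
      at$x[i], at$y[i], at$z[i], at$occ[i], at$b[i], at$element[i])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure as minimal mmCIF (atom_site loop)
#'
#' Fixture-grade writer: emits only the `atom_site` category with author
#' numbering, altloc and occupancy, enough to round-trip through
#' [load_structure()].
#'
#' @inheritParams write_pdb
#' @return `path`, invisibly.
#' @export
write_cif <- function(struct, path) {
  at <- rbind(struct$atom, struct$water)
  hdr <- c(paste0("data_", struct$id),
           "loop_",
           "_atom_site.group_PDB",
           "_atom_site.id",
           "_atom_site.type_symbol",
           "_atom_site.label_atom_id",
           "_atom_site.label_alt_id",
           "_atom_site.label_comp_id",
           "_atom_site.label_asym_id",
           "_atom_site.label_entity_id",
           "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x",
           "_atom_site.Cartn_y",
           "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv",
           "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(at)), function(i) {
    paste(at$record[i], i, at$element[i], at$atom[i],
          ifelse(at$alt[i] == "", ".", at$alt[i]),
          at$resname[i], at$chain[i], "1", at$resno[i],
          ifelse(at$ins[i] == "", "?", at$ins[i]),
          sprintf("%.3f", at$x[i]), sprintf("%.3f", at$y[i]),
          sprintf("%.3f", at$z[i]),
          sprintf("%.2f", at$occ[i]), sprintf("%.2f", at$b[i]),
          at$resno[i], at$resname[i], at$chain[i], at$atom[i], "1")
  }, character(1))
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
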