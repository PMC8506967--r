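# Join of the three analysis streams - contacts, superposition
# deviations, conservation tiers - into the headline artifacts:
# a contact-residue classification table, per-comparison deviation
# profiles, and an annotated alignment export; plus the config-driven
# pipeline orchestrator.

#' Classify contact residues by conservation tier and positioning
#'
#' Joins the contact residue set with conservation tiers (in the same
#' reference author numbering) and with per-comparison deviation
#' summaries.  Every contact residue appears exactly once, ordered by
#' residue number; residues without conservation data are flagged
#' `unscored` rather than dropped.
#'
#' @param contact_set From [contact_residue_set()].
#' @param footprint From [peptide_footprint()] (peptide residues
#'   contacted, aggregated per domain residue); optional.
#' @param tiers From [tier_columns()]; optional.
#' @param deviation_summaries Named list of [contact_deviation_summary()]
#'   outputs, one per comparison structure; optional.
#' @return Data frame (`bd_classification`): one row per contact
#'   residue with `kinds`, `bd_sides`, `pep_contacts`, `tier`, and per
#'   comparison `dev_<name>` / `identity_<name>` columns.
#' @export
build_classification <- function(contact_set, footprint = NULL,
                                 tiers = NULL,
                                 deviation_summaries = NULL) {
  out <- contact_set
  out$pep_contacts <- vapply(out$bd_resno, function(r) {
    if (is.null(footprint) || nrow(footprint) == 0) return("")
    hit <- footprint[footprint$bd_resno == r, ]
    paste(paste0(hit$pep_resname, hit$pep_resno), collapse = ",")
  }, character(1))
  out$tier <- vapply(out$bd_resno, function(r) {
    if (is.null(tiers)) return("unscored")
    i <- match(r, tiers$ref_resnum)
    if (is.na(i)) "unscored" else tiers$tier[i]
  }, character(1))
  for (nm in names(deviation_summaries)) {
    ds <- deviation_summaries[[nm]]
    i <- match(out$bd_resno, ds$ref_resno)
    out[[paste0("dev_", nm)]] <- ds$deviation[i]
    out[[paste0("identity_", nm)]] <- ds$identity_match[i]
  }
  out <- out[order(out$bd_resno, out$bd_ins), ]
  rownames(out) <- NULL
  class(out) <- c("bd_classification", class(out))
  out
}

#' Render an alignment with contact and conservation annotation lanes
#'
#' Produces a monospace text block: a contact lane (`^` under columns
#' whose reference residue contacts the peptide), a tier lane (`U`
#' universal, `F` family, `P` paralog, `.` none), a consensus lane
#' (two-residue consensus pairs are written `X1/X2` in a legend), then
#' the aligned rows.
#'
#' @param x A `bd_msa` with a reference row.
#' @param profile [conservation_profile()] of `x`.
#' @param contact_resnos Reference author numbers of contact residues.
#' @param tiers Optional [tier_columns()] output.
#' @return Character vector of lines.
#' @export
export_annotated_alignment <- function(x, profile, contact_resnos = integer(0),
                                       tiers = NULL) {
  if (is.null(attr(x, "ref_id"))) stop("alignment has no reference row")
  nc <- nchar(unclass(x)[[1]])
  contact_lane <- rep(" ", nc)
  contact_lane[profile$column[profile$ref_resnum %in% contact_resnos]] <- "^"
  tier_lane <- rep(" ", nc)
  if (!is.null(tiers)) {
    code <- c(universal = "U", family = "F", paralog = "P", none = ".")
    i <- match(profile$ref_resnum, tiers$ref_resnum)
    lane <- ifelse(is.na(i), " ", code[tiers$tier[i]])
    tier_lane[profile$column] <- ifelse(is.na(lane), " ", lane)
  }
  cons_lane <- vapply(profile$consensus, function(cc) {
    if (cc == "") " " else substr(cc, 1, 1)
  }, character(1))
  pairs <- profile$consensus[grepl("/", profile$consensus)]
  width <- max(nchar(names(x)), 9L) + 2L
  pad <- function(tag) formatC(tag, width = -width)
  lines <- c(paste0(pad("contact"), paste(contact_lane, collapse = "")),
             paste0(pad("tier"), paste(tier_lane, collapse = "")),
             paste0(pad("consensus"), paste(cons_lane, collapse = "")),
             vapply(names(x), function(id)
               paste0(pad(id), unclass(x)[[id]]), character(1)))
  if (length(pairs) > 0)
    lines <- c(lines, "", paste0("consensus pairs: ",
                                 paste(unique(pairs), collapse = " ")))
  unname(lines)
}

#' Run the full specificity pipeline from a configuration list
#'
#' Stages: load the reference complex; call direct and water-bridge
#' contacts; superpose each comparison structure onto the reference
#' with iterative pruning and summarise contact-residue deviations;
#' score conservation on each supplied alignment and tier the columns;
#' join everything into the classification table.  Outputs are plain
#' CSV/text and are byte-deterministic for fixed inputs; a run log
#' records every parameter and input checksum (no timestamps).  Any
#' stage failure removes partial outputs and aborts with the stage
#' name.
#'
#' @param config List with entries: `reference` (list `path`,
#'   `bd_chain`, `pep_chain`, optional `bd_range`, `pep_range`),
#'   `comparisons` (named list of lists `path`, `chain`), `msas`
#'   (named list with any of `paralog`, `family`, `universal`:
#'   lists `path`, `ref_id`, optional `ref_auth_start`), `params`
#'   (optional lists `contact`, `superpose`, `conservation`), and
#'   `out_dir`.
#' @return Invisibly, a list with the classification, contact records,
#'   superposition results, profiles and tier table; side effect: files
#'   under `out_dir`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir missing")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  log_lines <- character(0)
  emit <- function(stage, df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  log_param <- function(...) log_lines <<- c(log_lines, paste0(...))

  cp <- do.call(contact_params, config$params$contact %||% list())
  sp <- do.call(superpose_params, config$params$superpose %||% list())
  vp <- do.call(conservation_params, config$params$conservation %||% list())

  ref <- stage("load_reference", {
    rc <- config$reference
    if (is.null(rc$path) || !file.exists(rc$path))
      stop("reference structure file not found: ", rc$path %||% "<missing>")
    log_param("reference: ", rc$path, " md5=", tools::md5sum(rc$path))
    load_structure(rc$path)
  })
  rc <- config$reference
  bd_sel <- selection(rc$bd_chain, rc$bd_range[1], rc$bd_range[2])
  pep_sel <- selection(rc$pep_chain, rc$pep_range[1], rc$pep_range[2])

  contacts <- stage("contacts", {
    log_param("contact_params: direct=", cp$direct_cutoff,
              " hbond=", cp$hbond_cutoff)
    direct <- find_direct_contacts(ref, bd_sel, pep_sel, cp)
    bridges <- find_water_bridges(ref, bd_sel, pep_sel, cp)
    list(direct = direct, bridges = bridges,
         set = contact_residue_set(direct, bridges),
         footprint = peptide_footprint(direct, bridges))
  })
  emit("contacts", contacts$direct, "contacts_direct.csv")
  emit("contacts", contacts$bridges, "contacts_bridges.csv")

  bd_ref_atoms <- select_residues(ref, bd_sel)
  superpositions <- list()
  dev_summaries <- list()
  for (nm in names(config$comparisons)) {
    cmp <- config$comparisons[[nm]]
    res <- stage(paste0("superpose_", nm), {
      if (is.null(cmp$path) || !file.exists(cmp$path))
        stop("comparison structure file not found: ", cmp$path %||% "<missing>")
      log_param("comparison ", nm, ": ", cmp$path,
                " md5=", tools::md5sum(cmp$path),
                " prune=", sp$prune_cutoff)
      mob <- load_structure(cmp$path)
      mob_atoms <- select_residues(mob, selection(cmp$chain))
      iterative_prune_superpose(bd_ref_atoms, mob_atoms, params = sp)
    })
    superpositions[[nm]] <- res
    dev_summaries[[nm]] <-
      contact_deviation_summary(res, contacts$set$bd_resno)
    emit("profile", res$profile, paste0("profile_", nm, ".csv"))
  }

  profiles <- list()
  for (lvl in names(config$msas)) {
    mi <- config$msas[[lvl]]
    profiles[[lvl]] <- stage(paste0("conservation_", lvl), {
      if (is.null(mi$path) || !file.exists(mi$path))
        stop("alignment file not found: ", mi$path %||% "<missing>")
      log_param("msa ", lvl, ": ", mi$path, " md5=", tools::md5sum(mi$path),
                " threshold=", vp$similar_threshold,
                " nonsyn_max=", vp$nonsyn_max_fraction)
      m <- read_msa(mi$path, ref_id = mi$ref_id,
                    ref_auth_start = mi$ref_auth_start %||% 1L)
      conservation_profile(m, vp)
    })
    emit("conservation", profiles[[lvl]],
         paste0("conservation_", lvl, ".csv"))
  }
  tiers <- if (length(profiles) > 0)
    stage("tiering", tier_columns(profiles$paralog, profiles$family,
                                  profiles$universal))
  else NULL

  classification <- stage("classify", build_classification(
    contacts$set, contacts$footprint, tiers, dev_summaries))
  emit("classify", as.data.frame(classification), "classification.csv")

  if (!is.null(config$msas$paralog)) {
    ann <- stage("annotate", {
      mi <- config$msas$paralog
      m <- read_msa(mi$path, ref_id = mi$ref_id,
                    ref_auth_start = mi$ref_auth_start %||% 1L)
      export_annotated_alignment(m, profiles$paralog,
                                 contacts$set$bd_resno, tiers)
    })
    path <- file.path(out_dir, "annotated_alignment.txt")
    writeLines(ann, path)
    written <- c(written, path)
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(classification = classification, contacts = contacts,
                 superpositions = superpositions, profiles = profiles,
                 tiers = tiers, files = written))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
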