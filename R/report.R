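qsbench_version <- function() {
  as.character(utils::packageVersion("qsbench"))
}

as_struct_input <- function(x, extract_ligands = FALSE,
                            dict = ccd_dictionary()) {
  if (inherits(x, "struct")) return(x)
  read_structure(x, extract_ligands = extract_ligands, dict = dict)
}

score_or_null <- function(value, reason = NULL) {
  if (is.null(value) || (length(value) == 1 && is.na(value)))
    list(value = NULL, reason = reason %||% "not computable")
  else list(value = value)
}

#' Compare two structures: polymer scores
#'
#' Runs preprocessing (cleanup), sequence-based chain grouping, QSMap and/or
#' QSMapR chain mapping, and the requested polymer scores: LDDT, bb-LDDT,
#' i-LDDT, QS-score (global/best), ICS/IPS (plus trimmed variants), the
#' DockQ family with per-interface components and ave/wave aggregates, GDT
#' (TS/HA) and backbone RMSD. Individual score failures are reported as
#' null values with a reason; the run continues.
#'
#' @param reference,model `struct` objects or file paths (PDB/mmCIF).
#' @param scores character vector out of `"lddt"`, `"bb_lddt"`, `"ilddt"`,
#'   `"qs_score"`, `"ics_ips"`, `"dockq"`, `"gdt"`, `"rmsd"`.
#' @param residue_number_alignment pair residues by author numbering
#'   instead of sequence alignment.
#' @param dockq_capri_peptide CAPRI peptide parameterisation for DockQ only.
#' @param stereo_checks apply the stereochemistry filter to the model for
#'   LDDT variants.
#' @param identity_threshold model-to-group assignment threshold
#'   (`NULL` removes it).
#' @param mapping_params [mapping_params()]; @param dict dictionary.
#' @return `score_report` list: `meta`, `chain_mapping`, `scores`.
#' @export
compare_structures <- function(reference, model,
                               scores = c("lddt", "bb_lddt", "qs_score",
                                          "ics_ips", "dockq", "gdt",
                                          "rmsd"),
                               residue_number_alignment = FALSE,
                               dockq_capri_peptide = FALSE,
                               stereo_checks = FALSE,
                               identity_threshold = 0.70,
                               mapping_params = qsbench::mapping_params(),
                               dict = ccd_dictionary()) {
  params_aln <- alignment_params(
    mode = if (residue_number_alignment) "residue_number" else "sequence")
  ref <- cleanup_polymer(as_struct_input(reference, dict = dict), dict)
  mdl <- cleanup_polymer(as_struct_input(model, dict = dict), dict)
  groups <- group_reference_chains(ref, params_aln, dict)
  grouping <- assign_model_chains(mdl, groups, params_aln,
                                  identity_threshold, dict)
  out <- list(meta = list(tool = "qsbench", version = qsbench_version(),
                          scores = scores,
                          alignment_mode = params_aln$mode,
                          dockq_capri_peptide = dockq_capri_peptide,
                          identity_threshold = identity_threshold),
              scores = list())
  need_qsmap <- any(c("lddt", "bb_lddt", "ilddt", "qs_score", "ics_ips",
                      "dockq") %in% scores)
  need_qsmapr <- any(c("gdt", "rmsd") %in% scores)
  map_qs <- if (need_qsmap)
    tryCatch(qsmap(ref, mdl, grouping, mapping_params, params_aln, dict),
             warning = function(w) NULL, error = function(e) NULL)
  map_r <- if (need_qsmapr)
    tryCatch(qsmapr(ref, mdl, grouping, mapping_params, params_aln, dict),
             warning = function(w) NULL, error = function(e) NULL)
  out$chain_mapping <- list(
    qsmap = if (!is.null(map_qs)) unclass(map_qs),
    qsmapr = if (!is.null(map_r)) unclass(map_r))
  out$unmapped_model_chains <- grouping$unmapped_model_chains

  safe <- function(expr) tryCatch(expr, error = function(e)
    list(value = NULL, reason = conditionMessage(e)))
  add <- function(name, val) out$scores[[name]] <<- val

  if (!is.null(map_qs)) {
    if ("lddt" %in% scores)
      add("lddt", safe({
        r <- lddt_score(ref, mdl, map_qs, "full", params_aln = params_aln,
                        dict = dict,
                        stereo_lib = if (stereo_checks) stereo_library())
        score_or_null(r$score, r$reason)
      }))
    if ("bb_lddt" %in% scores)
      add("bb_lddt", safe({
        r <- lddt_score(ref, mdl, map_qs, "backbone",
                        params_aln = params_aln, dict = dict)
        score_or_null(r$score, r$reason)
      }))
    if ("ilddt" %in% scores)
      add("ilddt", safe({
        r <- lddt_score(ref, mdl, map_qs, "interface",
                        params_aln = params_aln, dict = dict)
        score_or_null(r$score, r$reason)
      }))
    if ("qs_score" %in% scores)
      add("qs", safe({
        r <- qs_score(ref, mdl, map_qs, params_aln, dict)
        list(qs_global = score_or_null(r$qs_global, r$reason),
             qs_best = score_or_null(r$qs_best, r$reason))
      }))
    if ("ics_ips" %in% scores)
      add("ics_ips", safe({
        r <- ics_ips(ref, mdl, map_qs, FALSE, params_aln, dict)
        rt <- ics_ips(ref, mdl, map_qs, TRUE, params_aln, dict)
        list(ics = score_or_null(r$ics, r$reason),
             ips = score_or_null(r$ips, r$reason),
             ics_trimmed = score_or_null(rt$ics, rt$reason),
             ips_trimmed = score_or_null(rt$ips, rt$reason),
             per_interface = r$per_interface)
      }))
    if ("dockq" %in% scores)
      add("dockq", safe({
        r <- dockq_all(ref, mdl, map_qs, dockq_capri_peptide, params_aln,
                       dict)
        list(dockq_ave = score_or_null(r$dockq_ave, r$reason),
             dockq_wave = score_or_null(r$dockq_wave, r$reason),
             per_interface = lapply(r$per_interface, function(x)
               x[c("interface", "fnat", "fnonnat", "irmsd", "lrmsd",
                   "dockq", "n_ref_contacts", "receptor")]))
      }))
  } else {
    for (nm in intersect(scores, c("lddt", "bb_lddt", "ilddt", "qs_score",
                                   "ics_ips", "dockq")))
      add(nm, list(value = NULL, reason = "no chain mapping"))
  }
  if (!is.null(map_r)) {
    if ("gdt" %in% scores)
      add("gdt", safe({
        r <- gdt(ref, mdl, map_r, params_aln = params_aln, dict = dict)
        list(gdt_ts = score_or_null(r$gdt_ts, r$reason),
             gdt_ha = score_or_null(r$gdt_ha, r$reason),
             fractions = as.list(r$fractions))
      }))
    if ("rmsd" %in% scores)
      add("rmsd", safe(score_or_null(
        backbone_rmsd(ref, mdl, map_r, params_aln, dict))))
  } else {
    for (nm in intersect(scores, c("gdt", "rmsd")))
      add(nm, list(value = NULL, reason = "no chain mapping"))
  }
  structure(out, class = "score_report")
}

#' Compare ligand poses between two structures
#'
#' Receptor structures are cleaned without replacing nonstandard residues.
#' Ligands come from SDF files or `lig` objects, or are extracted from
#' nonpolymer dictionary components of the input structures. All matching
#' reference/model ligand pairs (graph isomorphism, optional
#' reference-in-model substructure match) are scored with BiSyRMSD (plus
#' RMSD-LP and LDDT-LP) and LDDT-PLI, and one-to-one assignments are
#' generated independently for the two scores under the coverage rule.
#'
#' @param reference,model `struct`s or file paths.
#' @param reference_ligands,model_ligands lists of `lig` objects or SDF
#'   paths; `NULL` extracts ligands from the structures.
#' @param radius binding-site radius (A); @param lddt_pli_radius LDDT-PLI
#'   inclusion radius (A).
#' @param substructure_match allow reference-in-model subgraph matches.
#' @param coverage_delta assignment coverage window.
#' @param residue_number_alignment as in [compare_structures()].
#' @param dict dictionary.
#' @return `score_report` list with per-pair scores and both assignments.
#' @export
compare_ligand_structures <- function(reference, model,
                                      reference_ligands = NULL,
                                      model_ligands = NULL,
                                      radius = 4, lddt_pli_radius = 6,
                                      substructure_match = FALSE,
                                      coverage_delta = 0.2,
                                      residue_number_alignment = FALSE,
                                      dict = ccd_dictionary()) {
  params_aln <- alignment_params(
    mode = if (residue_number_alignment) "residue_number" else "sequence")
  ref_raw <- as_struct_input(reference, extract_ligands = TRUE, dict = dict)
  mdl_raw <- as_struct_input(model, extract_ligands = TRUE, dict = dict)
  get_ligs <- function(given, s) {
    if (is.null(given)) return(s$ligands)
    lapply(given, function(x)
      if (inherits(x, "lig")) x else read_ligand_sdf(x))
  }
  ref_ligs <- get_ligs(reference_ligands, ref_raw)
  mdl_ligs <- get_ligs(model_ligands, mdl_raw)
  ref <- cleanup_polymer(ref_raw, dict, replace_nonstandard = FALSE)
  mdl <- cleanup_polymer(mdl_raw, dict, replace_nonstandard = FALSE)
  uniq_names <- function(ligs) {
    nm <- vapply(ligs, `[[`, "", "name")
    make.unique(nm, sep = "#")
  }
  rnames <- uniq_names(ref_ligs); mnames <- uniq_names(mdl_ligs)
  rows <- list()
  details <- list()
  for (i in seq_along(ref_ligs)) for (j in seq_along(mdl_ligs)) {
    m <- match_ligands(ref_ligs[[i]], mdl_ligs[[j]],
                       allow_subgraph = substructure_match)
    if (is.null(m)) next
    bs <- bisy_rmsd(ref, mdl, ref_ligs[[i]], mdl_ligs[[j]], m, radius,
                    params_aln = params_aln, dict = dict)
    pli <- lddt_pli(ref, mdl, ref_ligs[[i]], mdl_ligs[[j]], m,
                    inclusion_radius = lddt_pli_radius,
                    params_aln = params_aln, dict = dict)
    rows[[length(rows) + 1L]] <- data.frame(
      ref = rnames[i], mdl = mnames[j], coverage = m$coverage,
      n_symmetries = length(m$correspondences),
      bisy_rmsd = bs$bisy_rmsd %||% NA_real_,
      rmsd_lp = bs$rmsd_lp %||% NA_real_,
      lddt_lp = bs$lddt_lp %||% NA_real_,
      lddt_pli = pli$lddt_pli %||% NA_real_,
      stringsAsFactors = FALSE)
    details[[paste(rnames[i], mnames[j])]] <-
      list(bisy = bs, pli = pli, match = m)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  report <- list(meta = list(tool = "qsbench", version = qsbench_version(),
                             radius = radius,
                             lddt_pli_radius = lddt_pli_radius,
                             substructure_match = substructure_match,
                             coverage_delta = coverage_delta,
                             alignment_mode = params_aln$mode),
                 pairs = tab)
  if (!is.null(tab)) {
    bt <- data.frame(ref = tab$ref, mdl = tab$mdl, score = tab$bisy_rmsd,
                     coverage = tab$coverage, stringsAsFactors = FALSE)
    pt <- data.frame(ref = tab$ref, mdl = tab$mdl, score = tab$lddt_pli,
                     coverage = tab$coverage, stringsAsFactors = FALSE)
    report$assignment_bisy_rmsd <- assign_ligands(bt, "min", coverage_delta)
    report$assignment_lddt_pli <- assign_ligands(pt, "max", coverage_delta)
  } else {
    report$assignment_bisy_rmsd <- report$assignment_lddt_pli <-
      list(pairs = NULL,
           unassigned_ref = rnames, unassigned_mdl = mnames)
  }
  report$details <- details
  structure(report, class = "score_report")
}

#' Write a score report as JSON
#'
#' @param report a `score_report`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  clean <- rapply(unclass(report), function(x)
    if (is.environment(x)) NULL else x, how = "replace")
  clean$details <- NULL
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE, pretty = TRUE)
  invisible(path)
}
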