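#' LDDT parameters
#'
#' @param inclusion_radius contact inclusion radius in Angstrom (default 15;
#'   use 30 when nucleotides are involved, whose backbone spacing is wider).
#' @param thresholds distance-difference thresholds in Angstrom.
#' @param variant `"full"` (all heavy atoms), `"backbone"` (representative
#'   backbone: CA for peptides, C3' for nucleotides) or `"interface"`
#'   (inter-chain contacts only).
#' @param stereo_checks apply the stereochemistry filter to the model before
#'   scoring (see [stereo_filter()]).
#' @return list of class `lddt_params`.
#' @export
lddt_params <- function(inclusion_radius = 15,
                        thresholds = c(0.5, 1, 2, 4),
                        variant = c("full", "backbone", "interface"),
                        stereo_checks = FALSE) {
  thresholds <- sort(thresholds)
  stopifnot(inclusion_radius > max(thresholds))
  structure(list(inclusion_radius = inclusion_radius,
                 thresholds = thresholds, variant = match.arg(variant),
                 stereo_checks = stereo_checks),
            class = "lddt_params")
}

backbone_rep_atom <- function(type) {
  ifelse(type == "nucleotide", "C3'", "CA")
}

# Atom selection for a contact table (heavy atoms; backbone variant keeps
# only representative backbone atoms).
lddt_atom_selection <- function(s, params, dict) {
  ty <- chain_types(s, dict)
  a <- s$atoms[s$atoms$elem != "H", , drop = FALSE]
  a <- a[ty[a$chain] %in% c("peptide", "nucleotide"), , drop = FALSE]
  if (params$variant == "backbone") {
    rep_at <- backbone_rep_atom(ty[a$chain])
    a <- a[a$atom == rep_at, , drop = FALSE]
  }
  a
}

#' Build the reference contact table for LDDT
#'
#' All (heavy) atom pairs within the inclusion radius, excluding pairs within
#' the same residue. The `interface` variant retains only pairs across
#' different chains.
#'
#' @param ref cleaned reference `struct`.
#' @param params [lddt_params()].
#' @param dict chemical component dictionary.
#' @return `contact_table`: atom table plus pair indices `i`, `j`, reference
#'   distances `d`, inter-chain flags.
#' @export
build_contact_table <- function(ref, params = lddt_params(),
                                dict = ccd_dictionary()) {
  a <- lddt_atom_selection(ref, params, dict)
  n <- nrow(a)
  if (n < 2) {
    return(structure(list(atoms = a, i = integer(), j = integer(),
                          d = double(), inter = logical(), params = params),
                     class = "contact_table"))
  }
  d <- cross_dist(coords(a), coords(a))
  rkey <- res_key(a)
  same_res <- outer(rkey, rkey, `==`)
  within <- d <= params$inclusion_radius & upper.tri(d) & !same_res
  if (params$variant == "interface")
    within <- within & outer(a$chain, a$chain, `!=`)
  hit <- which(within, arr.ind = TRUE)
  structure(list(atoms = a, i = hit[, 1], j = hit[, 2],
                 d = d[within],
                 inter = a$chain[hit[, 1]] != a$chain[hit[, 2]],
                 params = params),
            class = "contact_table")
}

# Hardcoded residue symmetries: atom-name permutations yielding chemically
# equivalent states. Nucleotide OP1/OP2 swaps included.
residue_symmetries <- function() {
  swap2 <- function(a, b) list(stats::setNames(c(b, a), c(a, b)))
  list(
    ASP = swap2("OD1", "OD2"),
    GLU = swap2("OE1", "OE2"),
    ARG = swap2("NH1", "NH2"),
    PHE = list(c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")),
    TYR = list(c(CD1 = "CD2", CD2 = "CD1", CE1 = "CE2", CE2 = "CE1")),
    A = swap2("OP1", "OP2"), C = swap2("OP1", "OP2"),
    G = swap2("OP1", "OP2"), U = swap2("OP1", "OP2"),
    DA = swap2("OP1", "OP2"), DC = swap2("OP1", "OP2"),
    DG = swap2("OP1", "OP2"), DT = swap2("OP1", "OP2")
  )
}

# Maps every atom of the reference contact table to a model atom index
# (NA when the model does not resolve it), honouring the chain mapping and
# per-chain residue correspondences.
map_table_atoms <- function(table, mdl, mapping, ref, params_aln, dict,
                            cache = NULL) {
  a <- table$atoms
  mk <- rep(NA_character_, nrow(a))
  matoms <- mdl$atoms
  mkey_full <- paste(res_key(matoms), matoms$atom)
  for (rch in names(mapping$pairs)) {
    mch <- mapping$pairs[[rch]]
    if (is.na(mch)) next
    corr <- chain_correspondence(ref, mdl, rch, mch, params_aln, dict, cache)
    sel <- which(a$chain == rch)
    if (!length(sel)) next
    rmap <- stats::setNames(corr$mdl_key, corr$ref_key)
    mk[sel] <- paste(rmap[res_key(a)[sel]], a$atom[sel])
  }
  match(mk, mkey_full)
}

#' LDDT score of a model against a reference contact table
#'
#' Fraction of reference contacts whose distance is preserved within each
#' threshold, averaged over thresholds. Contacts whose model atoms are
#' missing count as unpreserved. Residue naming symmetries (e.g. ASP
#' OD1/OD2, nucleotide OP1/OP2) are resolved greedily per residue to
#' maximise that residue's preserved contacts.
#'
#' @param mdl model `struct` (cleaned; optionally stereo-filtered when
#'   `params$stereo_checks`).
#' @param table [build_contact_table()] of the reference.
#' @param mapping `chain_mapping` (or a named character vector ref -> model
#'   chain ids).
#' @param ref the reference `struct` the table was built from.
#' @param params_aln [alignment_params()] used for residue correspondences.
#' @param dict chemical component dictionary.
#' @param stereo_lib stereochemistry library for the optional model filter.
#' @param symmetry resolve residue naming symmetries (disable to compare
#'   against symmetry-unaware references).
#' @return list: `score` (NA with `reason` when not computable), `per_residue`
#'   data frame, per-threshold `fractions`, contact counts.
#' @export
lddt <- function(mdl, table, mapping, ref,
                 params_aln = alignment_params(), dict = ccd_dictionary(),
                 stereo_lib = NULL, symmetry = TRUE) {
  if (is.character(mapping))
    mapping <- list(pairs = mapping)
  params <- table$params
  if (length(table$i) == 0) {
    return(list(score = NA_real_, reason = "no reference contacts",
                fractions = rep(NA_real_, length(params$thresholds)),
                n_contacts = 0L, per_residue = NULL))
  }
  if (isTRUE(params$stereo_checks)) {
    lib <- stereo_lib %||% stereo_library()
    mdl <- stereo_filter(mdl, lib, dict = dict)$structure
  }
  cache <- new.env(parent = emptyenv())
  midx <- map_table_atoms(table, mdl, mapping, ref, params_aln, dict, cache)
  mxyz <- coords(mdl$atoms)
  thr <- params$thresholds

  model_dist <- function(midx) {
    mi <- midx[table$i]; mj <- midx[table$j]
    ok <- !is.na(mi) & !is.na(mj)
    dm <- rep(NA_real_, length(table$i))
    dm[ok] <- sqrt(rowSums((mxyz[mi[ok], , drop = FALSE] -
                            mxyz[mj[ok], , drop = FALSE])^2))
    dm
  }
  preserved_matrix <- function(dm) {
    dd <- abs(dm - table$d)
    out <- vapply(thr, function(t) !is.na(dd) & dd <= t,
                  logical(length(dd)))
    matrix(out, ncol = length(thr))
  }

  # greedy per-residue symmetry resolution
  syms <- residue_symmetries()
  a <- table$atoms
  rkey <- res_key(a)
  sym_res <- if (symmetry) unique(rkey[a$resid %in% names(syms)])
             else character(0)
  dm <- model_dist(midx)
  for (rk in sym_res) {
    sel <- which(rkey == rk)
    resname <- a$resid[sel[1]]
    alts <- syms[[resname]]
    touches <- which(rkey[table$i] == rk | rkey[table$j] == rk)
    if (!length(touches)) next
    best_sc <- sum(preserved_matrix(dm)[touches, ])
    best_midx <- NULL
    for (perm in alts) {
      midx2 <- midx
      pos <- sel[match(names(perm), a$atom[sel])]
      src <- sel[match(unname(perm), a$atom[sel])]
      okp <- !is.na(pos) & !is.na(src)
      if (!any(okp)) next
      midx2[pos[okp]] <- midx[src[okp]]
      dm2 <- model_dist(midx2)
      sc <- sum(preserved_matrix(dm2)[touches, ])
      if (sc > best_sc) { best_sc <- sc; best_midx <- midx2 }
    }
    if (!is.null(best_midx)) { midx <- best_midx; dm <- model_dist(midx) }
  }

  pm <- preserved_matrix(dm)
  n <- length(table$d)
  fractions <- colSums(pm) / n
  score <- mean(fractions)

  # per-residue: every contact credited to both residues
  both_keys <- c(rkey[table$i], rkey[table$j])
  pr_pres <- rowsum(rep(rowSums(pm), 2), both_keys)
  pr_tot <- rowsum(rep(length(thr), 2 * n), both_keys)
  per_residue <- data.frame(key = rownames(pr_pres),
                            lddt = as.numeric(pr_pres / pr_tot),
                            stringsAsFactors = FALSE)
  list(score = score, fractions = fractions, n_contacts = n,
       preserved = colSums(pm), per_residue = per_residue)
}

#' Convenience wrapper computing LDDT variants for a mapped model
#'
#' @param ref,mdl cleaned structures.
#' @param mapping chain mapping (named vector or `chain_mapping`).
#' @param variant contact table variant, see [lddt_params()].
#' @param inclusion_radius `NULL` picks 15 (30 when nucleotides are present).
#' @param ... forwarded to [lddt()].
#' @param dict chemical component dictionary.
#' @return as [lddt()].
#' @export
lddt_score <- function(ref, mdl, mapping, variant = "full",
                       inclusion_radius = NULL, dict = ccd_dictionary(),
                       ...) {
  if (is.null(inclusion_radius)) {
    ty <- chain_types(ref, dict)
    inclusion_radius <- if (any(ty == "nucleotide")) 30 else 15
  }
  tab <- build_contact_table(ref, lddt_params(inclusion_radius,
                                              variant = variant), dict)
  lddt(mdl, tab, mapping, ref, dict = dict, ...)
}
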