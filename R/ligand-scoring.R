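# element-labelled molecular graph for igraph matching
ligand_graph <- function(lig, elem_levels) {
  g <- igraph::make_empty_graph(n = nrow(lig$atoms), directed = FALSE)
  if (nrow(lig$bonds))
    g <- igraph::add_edges(g, rbind(lig$bonds$a1, lig$bonds$a2))
  igraph::V(g)$color <- match(lig$atoms$elem, elem_levels)
  g
}

#' Match two ligands by graph isomorphism
#'
#' Ligands are compared as element-labelled molecular graphs; names play no
#' role. A full isomorphism is a match; with `allow_subgraph` the reference
#' graph may also match as a subgraph of the model graph (incomplete
#' reference density), never the other way around, so partial model ligands
#' do not match complete references. All one-to-one atom correspondences are
#' enumerated, capturing chemically equivalent symmetries (e.g. a benzene
#' ring yields 12).
#'
#' @param ref_lig,mdl_lig `lig` objects.
#' @param allow_subgraph allow reference-in-model subgraph matches.
#' @param max_symmetries error guard on the number of enumerated
#'   correspondences.
#' @return `ligand_match` (`correspondences`: list of integer vectors,
#'   reference atom i -> model atom index; `coverage`: fraction of model
#'   atoms covered) or `NULL` when the graphs do not match.
#' @export
match_ligands <- function(ref_lig, mdl_lig, allow_subgraph = FALSE,
                          max_symmetries = 1e5) {
  lv <- sort(unique(c(ref_lig$atoms$elem, mdl_lig$atoms$elem)))
  gr <- ligand_graph(ref_lig, lv)
  gm <- ligand_graph(mdl_lig, lv)
  nr <- nrow(ref_lig$atoms); nm <- nrow(mdl_lig$atoms)
  subgraph_mode <- FALSE
  if (nr == nm &&
      identical(sort(ref_lig$atoms$elem), sort(mdl_lig$atoms$elem))) {
    maps <- igraph::graph.get.isomorphisms.vf2(
      gr, gm, vertex.color1 = igraph::V(gr)$color,
      vertex.color2 = igraph::V(gm)$color)
    # vf2 reports the model-to-reference direction; invert to ref -> model
    maps <- lapply(maps, function(v) {
      v <- as.integer(v)
      inv <- integer(length(v)); inv[v] <- seq_along(v)
      inv
    })
  } else if (allow_subgraph && nr < nm) {
    subgraph_mode <- TRUE
    maps <- igraph::graph.get.subisomorphisms.vf2(
      gm, gr, vertex.color1 = igraph::V(gm)$color,
      vertex.color2 = igraph::V(gr)$color)
  } else maps <- list()
  if (!length(maps)) return(NULL)
  if (length(maps) > max_symmetries)
    stop("ligand symmetry enumeration produced ", length(maps),
         " correspondences; raise max_symmetries to proceed", call. = FALSE)
  structure(list(ref = ref_lig$name, mdl = mdl_lig$name,
                 correspondences = lapply(maps, as.integer),
                 coverage = nr / nm, subgraph_mode = subgraph_mode),
            class = "ligand_match")
}

#' Detect the reference binding site of a ligand
#'
#' Any polymer residue with at least one heavy atom within `radius` of any
#' ligand atom, based solely on the reference structure.
#'
#' @param ref reference `struct` (receptor cleanup keeps nonstandard
#'   residues for ligand scoring).
#' @param ref_lig reference `lig`.
#' @param radius site radius in Angstrom (default 4).
#' @param dict chemical component dictionary.
#' @return list `residues` (keys), `chains`, `radius`; empty `residues`
#'   flags the ligand as unscoreable for BiSyRMSD.
#' @export
detect_binding_site <- function(ref, ref_lig, radius = 4,
                                dict = ccd_dictionary()) {
  ty <- chain_types(ref, dict)
  a <- ref$atoms[ref$atoms$elem != "H" &
                   ty[ref$atoms$chain] %in% c("peptide", "nucleotide"), ,
                 drop = FALSE]
  if (!nrow(a))
    return(list(residues = character(0), chains = character(0),
                radius = radius))
  d <- cross_dist(coords(a), coords(ref_lig$atoms))
  hit <- apply(d, 1, min) <= radius
  keys <- unique(res_key(a)[hit])
  list(residues = keys, chains = unique(a$chain[res_key(a) %in% keys]),
       radius = radius)
}

# chains of `s` with >= 1 heavy atom within `radius` of the ligand
chains_near_ligand <- function(s, lig, radius, dict) {
  ty <- chain_types(s, dict)
  a <- s$atoms[s$atoms$elem != "H" &
                 ty[s$atoms$chain] %in% c("peptide", "nucleotide"), ,
               drop = FALSE]
  if (!nrow(a)) return(character(0))
  d <- cross_dist(coords(a), coords(lig$atoms))
  sort(unique(a$chain[apply(d, 1, min) <= radius]))
}

# Enumerate group-respecting mappings between a reference and model chain
# set for ligand scoring: returns list of named chr vectors (ref -> mdl).
ligand_chain_mappings <- function(ref, mdl, ref_chains, mdl_chains,
                                  params_aln, dict, cap = 1e4) {
  if (!length(ref_chains) || !length(mdl_chains)) return(list())
  sub <- ref
  sub$atoms <- ref$atoms[ref$atoms$chain %in% ref_chains, , drop = FALSE]
  if (!is.null(sub$entities))
    sub$entities <- sub$entities[sub$entities$chain %in% ref_chains, ,
                                 drop = FALSE]
  groups <- group_reference_chains(sub, params_aln, dict)
  msub <- mdl
  msub$atoms <- mdl$atoms[mdl$atoms$chain %in% mdl_chains, , drop = FALSE]
  grouping <- assign_model_chains(msub, groups, params_aln, dict = dict)
  per_group <- list()
  for (g in grouping$groups) {
    R <- g$ref_chains; M <- g$mdl_chains
    if (!length(R) || !length(M)) next
    if (length(R) <= length(M)) {
      inj <- all_injections(length(R), length(M))
      per_group[[length(per_group) + 1L]] <-
        lapply(seq_len(nrow(inj)), function(k)
          stats::setNames(M[inj[k, ]], R))
    } else {
      inj <- all_injections(length(M), length(R))
      per_group[[length(per_group) + 1L]] <-
        lapply(seq_len(nrow(inj)), function(k)
          stats::setNames(M, R[inj[k, ]]))
    }
  }
  if (!length(per_group)) return(list())
  total <- prod(vapply(per_group, length, 0))
  if (total > cap) {
    warning("chain mapping enumeration capped at ", cap, " of ", total)
  }
  grids <- do.call(expand.grid, c(lapply(per_group, seq_along),
                                  KEEP.OUT.ATTRS = FALSE))
  grids <- grids[seq_len(min(nrow(grids), cap)), , drop = FALSE]
  lapply(seq_len(nrow(grids)), function(row) {
    out <- character(0)
    for (gi in seq_along(per_group))
      out <- c(out, per_group[[gi]][[grids[row, gi]]])
    out
  })
}

not_computable <- function(reason) {
  list(value = NA_real_, reason = reason)
}

#' BiSyRMSD, RMSD-LP and LDDT-LP
#'
#' Binding-site superposed, symmetry-corrected ligand RMSD. The reference
#' binding site (residues within `radius` of the reference ligand) is
#' superposed onto the model via a Kabsch fit on CA (C3') atoms -- or all
#' backbone atoms when the site has two or fewer residues. For multi-chain
#' cases, model chains near the model ligand (lenient 25 A rule) are grouped
#' as for chain mapping and every group-respecting chain mapping is
#' evaluated; the best (lowest) BiSyRMSD over all mappings and all
#' symmetry-equivalent atom correspondences is reported. RMSD-LP is the
#' backbone RMSD of the site superposition for the reported mapping and
#' LDDT-LP the all-atom LDDT restricted to site residues under the same
#' mapping (defined as 0 for a single-residue site).
#'
#' @param ref,mdl receptor structures (cleaned with
#'   `replace_nonstandard = FALSE`).
#' @param ref_lig,mdl_lig ligands; @param match from [match_ligands()].
#' @param radius binding-site radius (A).
#' @param lenient_radius model chain inclusion radius (A).
#' @param params_aln [alignment_params()]; @param dict dictionary.
#' @return list `bisy_rmsd`, `rmsd_lp`, `lddt_lp`, `site`, `mapping`,
#'   or a not-computable result with `reason`.
#' @export
bisy_rmsd <- function(ref, mdl, ref_lig, mdl_lig, match, radius = 4,
                      lenient_radius = 25,
                      params_aln = alignment_params(),
                      dict = ccd_dictionary()) {
  if (is.null(match)) return(not_computable("ligands do not match"))
  site <- detect_binding_site(ref, ref_lig, radius, dict)
  if (!length(site$residues))
    return(not_computable("empty reference binding site"))
  mdl_chains <- chains_near_ligand(mdl, mdl_lig, lenient_radius, dict)
  if (!length(mdl_chains))
    return(not_computable("model binding site detection failed"))
  mappings <- ligand_chain_mappings(ref, mdl, site$chains, mdl_chains,
                                    params_aln, dict)
  if (!length(mappings))
    return(not_computable("no chain mapping between binding sites"))
  cache <- new.env(parent = emptyenv())
  ty <- chain_types(ref, dict)
  ref_xyz <- coords(ref_lig$atoms)
  mdl_xyz <- coords(mdl_lig$atoms)
  best <- NULL
  for (mp in mappings) {
    # paired site backbone coordinates under this mapping
    X <- NULL; Y <- NULL
    n_site_pairs <- 0L
    use_all_bb <- length(site$residues) <= 2
    for (rch in names(mp)) {
      res_here <- site$residues[startsWith(site$residues,
                                           paste0(rch, "|"))]
      if (!length(res_here)) next
      corr <- chain_correspondence(ref, mdl, rch, mp[[rch]], params_aln,
                                   dict, cache)
      rmap <- stats::setNames(corr$mdl_key, corr$ref_key)
      res_mapped <- res_here[res_here %in% names(rmap)]
      n_site_pairs <- n_site_pairs + length(res_mapped)
      bb <- if (use_all_bb) {
        if (ty[rch] == "nucleotide") nucleotide_backbone else peptide_backbone
      } else backbone_rep_atom(ty[rch])
      ra <- ref$atoms[res_key(ref$atoms) %in% res_mapped &
                        ref$atoms$atom %in% bb, , drop = FALSE]
      ma <- mdl$atoms
      mi <- match(paste(rmap[res_key(ra)], ra$atom),
                  paste(res_key(ma), ma$atom))
      ok <- !is.na(mi)
      X <- rbind(X, coords(ra)[ok, , drop = FALSE])
      Y <- rbind(Y, coords(ma)[mi[ok], , drop = FALSE])
    }
    if (is.null(X) || nrow(X) < 3) next
    fit <- kabsch(X, Y)
    mt <- fit$transform(mdl_xyz)
    rmsds <- vapply(match$correspondences, function(cr)
      rmsd_nofit(ref_xyz, mt[cr, , drop = FALSE]), 0)
    cand <- list(bisy = min(rmsds), rmsd_lp = fit$rmsd, mapping = mp,
                 n_site_pairs = n_site_pairs,
                 correspondence = match$correspondences[[which.min(rmsds)]])
    if (is.null(best) || cand$bisy < best$bisy - 1e-12) best <- cand
  }
  if (is.null(best))
    return(not_computable("binding site superposition not possible"))

  # LDDT-LP: all-atom LDDT restricted to site residues, same mapping
  lddt_lp <- if (best$n_site_pairs <= 1) 0 else {
    sub <- ref
    sub$atoms <- ref$atoms[res_key(ref$atoms) %in% site$residues, ,
                           drop = FALSE]
    tab <- build_contact_table(sub, lddt_params(variant = "full"), dict)
    if (length(tab$i) == 0) NA_real_
    else lddt(mdl, tab, best$mapping, ref, params_aln, dict)$score
  }
  list(bisy_rmsd = best$bisy, rmsd_lp = best$rmsd_lp, lddt_lp = lddt_lp,
       site = site, mapping = best$mapping,
       correspondence = best$correspondence)
}

#' LDDT-PLI: LDDT over polymer-ligand interactions
#'
#' A symmetry-corrected LDDT on pairwise distances between ligand atoms and
#' polymer atoms, with a reduced inclusion radius (6 A) and standard
#' thresholds (0.5/1/2/4 A). Unlike classical LDDT, contacts found only in
#' the model are added to the assessed set when both atoms can be mapped to
#' the reference, penalising contact overprediction. Chains with any atom
#' within the inclusion radius plus the maximum threshold (10 A) of the
#' ligand are considered; chain mappings, ligand symmetries and polymer
#' residue symmetries are enumerated jointly and the best score is
#' reported. No stereochemistry checks are applied.
#'
#' @inheritParams bisy_rmsd
#' @param inclusion_radius contact radius (A), default 6.
#' @param max_states cap on (chain mapping x ligand symmetry) states.
#' @return list `lddt_pli`, `n_contacts`, `mapping`, or not-computable.
#' @export
lddt_pli <- function(ref, mdl, ref_lig, mdl_lig, match,
                     inclusion_radius = 6,
                     params_aln = alignment_params(),
                     dict = ccd_dictionary(), max_states = 1e5) {
  if (is.null(match)) return(not_computable("ligands do not match"))
  thr <- c(0.5, 1, 2, 4)
  reach <- inclusion_radius + max(thr)
  ref_chains <- chains_near_ligand(ref, ref_lig, reach, dict)
  mdl_chains <- chains_near_ligand(mdl, mdl_lig, reach, dict)
  if (!length(ref_chains) && !length(mdl_chains))
    return(not_computable("no polymer chains near either ligand"))
  # borrow chemically equivalent reference chains when the model brings
  # more contacting chains than the reference site offers (closest to the
  # reference ligand by centre of mass)
  all_ref <- ligand_chain_mappings(ref, mdl,
                                   union(ref_chains,
                                         borrow_equivalents(ref, mdl,
                                                            ref_chains,
                                                            mdl_chains,
                                                            ref_lig,
                                                            params_aln,
                                                            dict)),
                                   mdl_chains, params_aln, dict)
  if (!length(all_ref))
    return(not_computable("no chain mapping near the ligand"))
  ty <- chain_types(ref, dict)
  ra <- ref$atoms[ref$atoms$elem != "H" &
                    ty[ref$atoms$chain] %in% c("peptide", "nucleotide"), ,
                  drop = FALSE]
  ma_all <- mdl$atoms
  mkey_all <- paste(res_key(ma_all), ma_all$atom)
  r_xyz <- coords(ra)
  rl_xyz <- coords(ref_lig$atoms)
  ml_xyz <- coords(mdl_lig$atoms)
  dr_all <- cross_dist(rl_xyz, r_xyz)          # ref ligand x ref polymer
  cache <- new.env(parent = emptyenv())
  n_states <- length(all_ref) * length(match$correspondences)
  if (n_states > max_states)
    warning("LDDT-PLI state enumeration capped at ", max_states)
  best <- NULL
  states <- 0L
  for (mp in all_ref) {
    # ref polymer atom key -> model atom row
    rmap <- character(0)
    for (rch in names(mp)) {
      corr <- chain_correspondence(ref, mdl, rch, mp[[rch]], params_aln,
                                   dict, cache)
      rmap[corr$ref_key] <- corr$mdl_key
    }
    mrow <- match(paste(rmap[res_key(ra)], ra$atom), mkey_all)
    # reverse: model atom row -> ref polymer atom index
    rev <- rep(NA_integer_, nrow(ma_all))
    rev[mrow[!is.na(mrow)]] <- which(!is.na(mrow))
    dm_all <- cross_dist(ml_xyz, coords(ma_all))  # mdl ligand x mdl atoms
    for (cr in match$correspondences) {
      states <- states + 1L
      if (states > max_states) break
      # union contact set in reference space: (ref lig atom, ref poly atom)
      rhit <- which(dr_all <= inclusion_radius, arr.ind = TRUE)
      ids <- paste(rhit[, 1], rhit[, 2])
      # model contacts with both atoms mappable
      mhit <- which(dm_all <= inclusion_radius, arr.ind = TRUE)
      if (nrow(mhit)) {
        ref_poly <- rev[mhit[, 2]]
        inv <- integer(nrow(mdl_lig$atoms)); inv[cr] <- seq_along(cr)
        ref_ligat <- inv[mhit[, 1]]
        okm <- !is.na(ref_poly) & ref_ligat > 0
        ids <- union(ids, paste(ref_ligat[okm], ref_poly[okm]))
      }
      if (!length(ids)) next
      parts <- matrix(as.integer(unlist(strsplit(ids, " "))),
                      ncol = 2, byrow = TRUE)
      dr <- dr_all[parts]
      mpoly <- mrow[parts[, 2]]
      mlig <- cr[parts[, 1]]
      okd <- !is.na(mpoly)
      dm <- rep(NA_real_, nrow(parts))
      dm[okd] <- sqrt(rowSums((ml_xyz[mlig[okd], , drop = FALSE] -
                                 coords(ma_all)[mpoly[okd], ,
                                                drop = FALSE])^2))
      dd <- abs(dm - dr)
      pres <- sum(vapply(thr, function(t)
        sum(!is.na(dd) & dd <= t), 0L))
      sc <- pres / (4 * nrow(parts))
      # polymer residue symmetry: greedy per-residue swap
      sc <- max(sc, pli_symmetry_pass(ra, parts, dr, mrow, mlig, ml_xyz,
                                      ma_all, thr))
      if (is.null(best) || sc > best$score + 1e-12)
        best <- list(score = sc, n = nrow(parts), mapping = mp)
    }
  }
  if (is.null(best))
    return(not_computable("no polymer-ligand contacts"))
  list(lddt_pli = best$score, n_contacts = best$n, mapping = best$mapping)
}

# one greedy pass over residues with symmetric atom naming, swapping the
# model atom assignment where it improves the preserved-contact count
pli_symmetry_pass <- function(ra, parts, dr, mrow, mlig, ml_xyz, ma_all,
                              thr) {
  syms <- residue_symmetries()
  rkeys <- res_key(ra)[parts[, 2]]
  resnames <- ra$resid[parts[, 2]]
  cand_res <- unique(rkeys[resnames %in% names(syms)])
  score_of <- function(mrow2) {
    mpoly <- mrow2[parts[, 2]]
    okd <- !is.na(mpoly)
    dm <- rep(NA_real_, nrow(parts))
    dm[okd] <- sqrt(rowSums((ml_xyz[mlig[okd], , drop = FALSE] -
                               coords(ma_all)[mpoly[okd], ,
                                              drop = FALSE])^2))
    dd <- abs(dm - dr)
    sum(vapply(thr, function(t) sum(!is.na(dd) & dd <= t), 0L)) /
      (4 * nrow(parts))
  }
  if (!length(cand_res)) return(score_of(mrow))
  cur <- mrow
  for (rk in cand_res) {
    sel <- which(res_key(ra) == rk)
    resname <- ra$resid[sel[1]]
    base <- score_of(cur)
    for (perm in syms[[resname]]) {
      alt <- cur
      pos <- sel[match(names(perm), ra$atom[sel])]
      src <- sel[match(unname(perm), ra$atom[sel])]
      okp <- !is.na(pos) & !is.na(src)
      if (!any(okp)) next
      alt[pos[okp]] <- cur[src[okp]]
      if (score_of(alt) > base) { cur <- alt; break }
    }
  }
  score_of(cur)
}

borrow_equivalents <- function(ref, mdl, ref_chains, mdl_chains, ref_lig,
                               params_aln, dict) {
  # when more model chains contact the ligand than reference chains are
  # available, pull in equivalent reference chains closest to the ligand
  extra <- length(mdl_chains) - length(ref_chains)
  if (extra <= 0) return(character(0))
  ty <- chain_types(ref, dict)
  pool <- setdiff(names(ty)[ty %in% c("peptide", "nucleotide")], ref_chains)
  if (!length(pool)) return(character(0))
  lig_com <- colMeans(coords(ref_lig$atoms))
  d <- vapply(pool, function(ch) {
    a <- ref$atoms[ref$atoms$chain == ch, , drop = FALSE]
    sqrt(sum((colMeans(coords(a)) - lig_com)^2))
  }, 0)
  pool[order(d)][seq_len(min(extra, length(pool)))]
}

#' Greedy one-to-one ligand assignment
#'
#' Iteratively assigns the best-scoring pair of matching reference and model
#' ligands until none remain. In each iteration candidates are limited to
#' pairs with coverage greater than the current maximum coverage minus
#' `coverage_delta`, which discourages assignments of small solvent
#' fragments over full matches. Ties prefer higher coverage, then
#' lexicographic ligand ids. Assignments for different scores (lowest
#' BiSyRMSD, highest LDDT-PLI) are generated independently.
#'
#' @param score_table data frame with columns `ref`, `mdl`, `score`,
#'   `coverage` (one row per matching pair; NA scores are skipped).
#' @param objective `"min"` (RMSD-like) or `"max"` (LDDT-like).
#' @param coverage_delta coverage window (default 0.2).
#' @return list `pairs` (data frame), `unassigned_ref`, `unassigned_mdl`.
#' @export
assign_ligands <- function(score_table, objective = c("min", "max"),
                           coverage_delta = 0.2) {
  objective <- match.arg(objective)
  st <- score_table[!is.na(score_table$score), , drop = FALSE]
  assigned <- st[0, , drop = FALSE]
  repeat {
    cand <- st[!(st$ref %in% assigned$ref) &
                 !(st$mdl %in% assigned$mdl), , drop = FALSE]
    if (!nrow(cand)) break
    cov_max <- max(cand$coverage)
    cand <- cand[cand$coverage > cov_max - coverage_delta, , drop = FALSE]
    ord <- if (objective == "min")
      order(cand$score, -cand$coverage, cand$ref, cand$mdl)
    else order(-cand$score, -cand$coverage, cand$ref, cand$mdl)
    assigned <- rbind(assigned, cand[ord[1], , drop = FALSE])
  }
  rownames(assigned) <- NULL
  list(pairs = assigned,
       unassigned_ref = setdiff(unique(score_table$ref), assigned$ref),
       unassigned_mdl = setdiff(unique(score_table$mdl), assigned$mdl))
}
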