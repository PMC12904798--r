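# Residue-level representative positions for interface contact scores:
# CB (CA for glycine) for peptides, C3' for nucleotides.
rep_positions <- function(s, dict = ccd_dictionary()) {
  ty <- chain_types(s, dict)
  a <- s$atoms[ty[s$atoms$chain] %in% c("peptide", "nucleotide"), ,
               drop = FALSE]
  want <- ifelse(ty[a$chain] == "nucleotide", "C3'",
                 ifelse(a$resid == "GLY", "CA", "CB"))
  sel <- a$atom == want
  # fall back to CA when CB is missing on a non-glycine residue
  have <- res_key(a)[sel]
  ca <- a$atom == "CA" & !(res_key(a) %in% have) &
    ty[a$chain] == "peptide"
  a <- a[sel | ca, , drop = FALSE]
  data.frame(chain = a$chain, key = res_key(a),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

# Interface contacts between representative positions of two chains.
# Returns data.frame(key1, key2, d) with d <= radius.
chain_pair_contacts <- function(rp, c1, c2, radius = 12) {
  p1 <- rp[rp$chain == c1, , drop = FALSE]
  p2 <- rp[rp$chain == c2, , drop = FALSE]
  if (!nrow(p1) || !nrow(p2))
    return(data.frame(key1 = character(), key2 = character(), d = double()))
  d <- cross_dist(cbind(p1$x, p1$y, p1$z), cbind(p2$x, p2$y, p2$z))
  hit <- which(d <= radius, arr.ind = TRUE)
  data.frame(key1 = p1$key[hit[, 1]], key2 = p2$key[hit[, 2]],
             d = d[hit], stringsAsFactors = FALSE)
}

# All interface contacts of a structure as data.frame(chain1, chain2,
# key1, key2, d), chains ordered lexicographically.
all_interface_contacts <- function(s, dict = ccd_dictionary(), radius = 12) {
  rp <- rep_positions(s, dict)
  chains <- sort(unique(rp$chain))
  out <- list()
  if (length(chains) >= 2) {
    for (i in seq_along(chains)) for (j in seq_along(chains)) {
      if (j <= i) next
      cc <- chain_pair_contacts(rp, chains[i], chains[j], radius)
      if (nrow(cc)) {
        cc$chain1 <- chains[i]; cc$chain2 <- chains[j]
        out[[length(out) + 1L]] <- cc
      }
    }
  }
  if (!length(out))
    return(data.frame(key1 = character(), key2 = character(), d = double(),
                      chain1 = character(), chain2 = character()))
  do.call(rbind, out)
}

#' QS-score: quaternary-structure contact overlap
#'
#' Contacts are residue pairs from different chains whose representative
#' positions (CB, CA for glycine; C3' for nucleotides) lie within 12 A.
#' A contact present in both structures contributes
#' `w = max(0, 1 - |d_ref - d_mdl| / 12)`. `qs_global` divides by the union
#' of contacts in either structure (penalising contacts unique to one side,
#' including unmapped chains) and is symmetric under model/reference
#' exchange; `qs_best` divides only by union contacts among residues
#' resolved in both structures, so incomplete models or wrong stoichiometry
#' are not penalised.
#'
#' @param ref,mdl cleaned structures.
#' @param mapping `chain_mapping` or named character vector (ref -> model).
#' @param params_aln [alignment_params()].
#' @param dict chemical component dictionary.
#' @param radius contact radius in Angstrom.
#' @return list `qs_global`, `qs_best` (NA with `reason` when neither
#'   structure has interface contacts).
#' @export
qs_score <- function(ref, mdl, mapping, params_aln = alignment_params(),
                     dict = ccd_dictionary(), radius = 12) {
  if (is.character(mapping)) mapping <- list(pairs = mapping)
  rc <- all_interface_contacts(ref, dict, radius)
  mc <- all_interface_contacts(mdl, dict, radius)
  if (!nrow(rc) && !nrow(mc))
    return(list(qs_global = NA_real_, qs_best = NA_real_,
                reason = "no interface contacts in either structure"))
  cache <- new.env(parent = emptyenv())
  pairs <- mapping$pairs[!is.na(mapping$pairs)]

  # residue-key translation model -> reference, and resolved-residue sets
  m2r <- character(0)
  ref_resolved <- character(0)   # ref residue keys with a model counterpart
  for (rch in names(pairs)) {
    corr <- chain_correspondence(ref, mdl, rch, pairs[[rch]], params_aln,
                                 dict, cache)
    m2r[corr$mdl_key] <- corr$ref_key
    ref_resolved <- c(ref_resolved, corr$ref_key)
  }

  cid <- function(k1, k2) ifelse(k1 < k2, paste(k1, k2), paste(k2, k1))
  rid <- cid(rc$key1, rc$key2)
  mk1 <- m2r[mc$key1]; mk2 <- m2r[mc$key2]
  translatable <- !is.na(mk1) & !is.na(mk2)
  mid <- rep(NA_character_, nrow(mc))
  mid[translatable] <- cid(mk1[translatable], mk2[translatable])

  shared <- match(rid, mid)
  is_shared <- !is.na(shared)
  w <- numeric(nrow(rc))
  w[is_shared] <- pmax(0, 1 - abs(rc$d[is_shared] -
                                    mc$d[shared[is_shared]]) / radius)
  num <- sum(w)
  n_union <- nrow(rc) + sum(!(mid %in% rid) | is.na(mid))

  both_resolved_ref <- rc$key1 %in% ref_resolved & rc$key2 %in% ref_resolved
  mdl_extra_resolved <- translatable & !(mid %in% rid)
  n_best <- sum(both_resolved_ref) + sum(mdl_extra_resolved)

  list(qs_global = if (n_union > 0) num / n_union else NA_real_,
       qs_best = if (n_best > 0) num / n_best else NA_real_)
}
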