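# Residue-residue contacts across chains: any heavy-atom pair closer than
# `radius`. Returns data.frame(chain1, chain2, key1, key2) with chain1<chain2.
residue_contacts <- function(s, dict, radius = 5,
                             keep_residues = NULL) {
  ty <- chain_types(s, dict)
  a <- s$atoms[s$atoms$elem != "H" &
                 ty[s$atoms$chain] %in% c("peptide", "nucleotide"), ,
               drop = FALSE]
  if (!is.null(keep_residues))
    a <- a[res_key(a) %in% keep_residues, , drop = FALSE]
  chains <- sort(unique(a$chain))
  out <- list()
  for (i in seq_along(chains)) for (j in seq_along(chains)) {
    if (j <= i) next
    a1 <- a[a$chain == chains[i], , drop = FALSE]
    a2 <- a[a$chain == chains[j], , drop = FALSE]
    d <- cross_dist(coords(a1), coords(a2))
    hit <- which(d < radius, arr.ind = TRUE)
    if (!nrow(hit)) next
    cc <- unique(data.frame(key1 = res_key(a1)[hit[, 1]],
                            key2 = res_key(a2)[hit[, 2]],
                            stringsAsFactors = FALSE))
    cc$chain1 <- chains[i]; cc$chain2 <- chains[j]
    out[[length(out) + 1L]] <- cc
  }
  if (!length(out))
    return(data.frame(key1 = character(), key2 = character(),
                      chain1 = character(), chain2 = character()))
  do.call(rbind, out)
}

# model residue key -> reference residue key over all mapped chains
model_to_ref_map <- function(ref, mdl, mapping, params_aln, dict,
                             cache = NULL) {
  pairs <- if (is.character(mapping)) mapping else mapping$pairs
  pairs <- pairs[!is.na(pairs)]
  m2r <- character(0)
  for (rch in names(pairs)) {
    corr <- chain_correspondence(ref, mdl, rch, pairs[[rch]], params_aln,
                                 dict, cache)
    m2r[corr$mdl_key] <- corr$ref_key
  }
  m2r
}

#' ICS and IPS: interface contact and patch similarity
#'
#' Contacts are residue pairs from different chains with any heavy-atom pair
#' closer than `radius` (default 5 A). ICS is the F1 score of model versus
#' reference contact sets (model contacts translated into reference residue
#' space; untranslatable contacts count against precision). IPS is the
#' Jaccard similarity of the interface residue sets. The trimmed variants
#' first remove model residues that have no reference counterpart, so
#' regions absent from an incomplete reference are not penalised. Scores for
#' the full complex pool all contacts; per-interface scores are reported per
#' mapped chain pair.
#'
#' @param ref,mdl cleaned structures.
#' @param mapping chain mapping (named vector or `chain_mapping`).
#' @param trimmed compute the trimmed variant.
#' @param params_aln [alignment_params()]; @param dict dictionary.
#' @param radius heavy-atom contact radius (A).
#' @return list `ics`, `ips`, `per_interface` data frame; NAs with `reason`
#'   when neither structure has contacts.
#' @export
ics_ips <- function(ref, mdl, mapping, trimmed = FALSE,
                    params_aln = alignment_params(),
                    dict = ccd_dictionary(), radius = 5) {
  cache <- new.env(parent = emptyenv())
  m2r <- model_to_ref_map(ref, mdl, mapping, params_aln, dict, cache)
  rc <- residue_contacts(ref, dict, radius)
  keep <- if (trimmed) names(m2r) else NULL
  mc <- residue_contacts(mdl, dict, radius, keep_residues = keep)
  if (!nrow(rc) && !nrow(mc))
    return(list(ics = NA_real_, ips = NA_real_,
                reason = "no interface contacts in either structure",
                per_interface = NULL))
  tr <- function(k) ifelse(k %in% names(m2r), m2r[k], paste0("mdl:", k))
  cid <- function(k1, k2) ifelse(k1 < k2, paste(k1, k2), paste(k2, k1))
  rid <- cid(rc$key1, rc$key2)
  mid <- cid(tr(mc$key1), tr(mc$key2))
  f1 <- function(rid, mid) {
    shared <- sum(mid %in% rid)
    p <- if (length(mid)) shared / length(mid) else 0
    r <- if (length(rid)) shared / length(rid) else 0
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  jac <- function(rres, mres) {
    u <- union(rres, mres)
    if (!length(u)) return(0)
    length(intersect(rres, mres)) / length(u)
  }
  ics <- f1(rid, mid)
  ips <- jac(unique(c(rc$key1, rc$key2)),
             unique(c(tr(mc$key1), tr(mc$key2))))
  # per mapped reference chain pair
  pairs <- if (is.character(mapping)) mapping else mapping$pairs
  pairs <- pairs[!is.na(pairs)]
  per <- list()
  rpair <- t(utils::combn(sort(names(pairs)), min(2, length(pairs))))
  if (length(pairs) >= 2) for (k in seq_len(nrow(rpair))) {
    c1 <- rpair[k, 1]; c2 <- rpair[k, 2]
    ri <- rid[(rc$chain1 == c1 & rc$chain2 == c2) |
                (rc$chain1 == c2 & rc$chain2 == c1)]
    mm <- sort(c(pairs[[c1]], pairs[[c2]]))
    mi <- mid[(mc$chain1 == mm[1] & mc$chain2 == mm[2])]
    if (!length(ri) && !length(mi)) next
    per[[length(per) + 1L]] <- data.frame(
      ref_chain1 = c1, ref_chain2 = c2,
      ics = f1(ri, mi), n_ref_contacts = length(ri),
      n_mdl_contacts = length(mi), stringsAsFactors = FALSE)
  }
  list(ics = ics, ips = ips,
       per_interface = if (length(per)) do.call(rbind, per) else NULL)
}

dockq_backbone <- c("N", "CA", "C", "O")
dockq_backbone_nuc <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

# paired backbone coordinates for given ref residues of one chain
paired_backbone <- function(ref, mdl, rch, mch, res_keys, corr, dict) {
  ty <- chain_types(ref, dict)[rch]
  bb <- if (ty == "nucleotide") dockq_backbone_nuc else dockq_backbone
  ra <- ref$atoms[ref$atoms$chain == rch, , drop = FALSE]
  ra <- ra[res_key(ra) %in% res_keys & ra$atom %in% bb, , drop = FALSE]
  rmap <- stats::setNames(corr$mdl_key, corr$ref_key)
  mk <- paste(rmap[res_key(ra)], ra$atom)
  ma <- mdl$atoms
  mi <- match(mk, paste(res_key(ma), ma$atom))
  ok <- !is.na(mi)
  list(x = coords(ra)[ok, , drop = FALSE],
       y = coords(ma)[mi[ok], , drop = FALSE])
}

#' DockQ and its components for one dimeric interface
#'
#' fnat is the fraction of reference interface contacts (heavy-atom residue
#' contacts, 5 A; 4 A with `capri_peptide`) recovered by the model; i-RMSD
#' the backbone RMSD over interface residues (within 10 A of the partner
#' chain; 8 A, CA-based with `capri_peptide`) after interface superposition;
#' L-RMSD the backbone RMSD of the smaller ("ligand") chain after
#' superposing the larger ("receptor") chain. DockQ combines them as
#' `(fnat + 1/(1+(iRMSD/1.5)^2) + 1/(1+(LRMSD/8.5)^2)) / 3`.
#'
#' @param ref,mdl cleaned structures.
#' @param mapping chain mapping covering both interface chains.
#' @param interface character vector of the two reference chain ids.
#' @param capri_peptide use the CAPRI peptide parameterisation.
#' @param params_aln [alignment_params()]; @param dict dictionary.
#' @return list `fnat`, `fnonnat`, `irmsd`, `lrmsd`, `dockq`,
#'   `n_ref_contacts`, `receptor`.
#' @export
dockq <- function(ref, mdl, mapping, interface, capri_peptide = FALSE,
                  params_aln = alignment_params(),
                  dict = ccd_dictionary()) {
  pairs <- if (is.character(mapping)) mapping else mapping$pairs
  c1 <- interface[1]; c2 <- interface[2]
  if (!all(c(c1, c2) %in% names(pairs)))
    return(list(dockq = NA_real_, reason = "interface chains not mapped"))
  contact_r <- if (capri_peptide) 4 else 5
  iface_r <- if (capri_peptide) 8 else 10
  cache <- new.env(parent = emptyenv())
  corr1 <- chain_correspondence(ref, mdl, c1, pairs[[c1]], params_aln,
                                dict, cache)
  corr2 <- chain_correspondence(ref, mdl, c2, pairs[[c2]], params_aln,
                                dict, cache)

  heavy <- function(s, ch, atom_sel = NULL) {
    a <- s$atoms[s$atoms$chain == ch & s$atoms$elem != "H", , drop = FALSE]
    if (!is.null(atom_sel)) a <- a[a$atom %in% atom_sel, , drop = FALSE]
    a
  }
  contacts_between <- function(s, ch1, ch2, radius) {
    a1 <- heavy(s, ch1); a2 <- heavy(s, ch2)
    d <- cross_dist(coords(a1), coords(a2))
    hit <- which(d < radius, arr.ind = TRUE)
    unique(data.frame(k1 = res_key(a1)[hit[, 1]],
                      k2 = res_key(a2)[hit[, 2]], stringsAsFactors = FALSE))
  }
  rc <- contacts_between(ref, c1, c2, contact_r)
  mcon <- contacts_between(mdl, pairs[[c1]], pairs[[c2]], contact_r)
  map1 <- stats::setNames(corr1$ref_key, corr1$mdl_key)
  map2 <- stats::setNames(corr2$ref_key, corr2$mdl_key)
  mid <- paste(map1[mcon$k1], map2[mcon$k2])
  rid <- paste(rc$k1, rc$k2)
  fnat <- if (nrow(rc)) sum(mid %in% rid) / nrow(rc) else NA_real_
  fnonnat <- if (nrow(mcon)) sum(!(mid %in% rid) | is.na(mid)) / nrow(mcon)
             else 0

  # interface residues in the reference
  if (capri_peptide) {
    rp <- rep_positions(ref, dict)
    p1 <- rp[rp$chain == c1, , drop = FALSE]
    p2 <- rp[rp$chain == c2, , drop = FALSE]
    d <- cross_dist(cbind(p1$x, p1$y, p1$z), cbind(p2$x, p2$y, p2$z))
    hit <- which(d < iface_r, arr.ind = TRUE)
    ires1 <- unique(p1$key[hit[, 1]]); ires2 <- unique(p2$key[hit[, 2]])
  } else {
    icon <- contacts_between(ref, c1, c2, iface_r)
    ires1 <- unique(icon$k1); ires2 <- unique(icon$k2)
  }
  pb1 <- paired_backbone(ref, mdl, c1, pairs[[c1]], ires1, corr1, dict)
  pb2 <- paired_backbone(ref, mdl, c2, pairs[[c2]], ires2, corr2, dict)
  X <- rbind(pb1$x, pb2$x); Y <- rbind(pb1$y, pb2$y)
  irmsd <- if (nrow(X) >= 3) kabsch(X, Y)$rmsd else NA_real_

  # receptor = larger chain; L-RMSD on the other chain after receptor fit
  n1 <- nrow(chain_residues(ref, c1)); n2 <- nrow(chain_residues(ref, c2))
  rec <- if (n2 > n1) c2 else c1
  lig <- setdiff(c(c1, c2), rec)
  corr_rec <- if (rec == c1) corr1 else corr2
  corr_lig <- if (rec == c1) corr2 else corr1
  all_rec <- chain_residues(ref, rec)$key
  all_lig <- chain_residues(ref, lig)$key
  pr <- paired_backbone(ref, mdl, rec, pairs[[rec]], all_rec, corr_rec, dict)
  pl <- paired_backbone(ref, mdl, lig, pairs[[lig]], all_lig, corr_lig, dict)
  lrmsd <- if (nrow(pr$x) >= 3 && nrow(pl$x) >= 1) {
    fit <- kabsch(pr$x, pr$y)
    rmsd_nofit(pl$x, fit$transform(pl$y))
  } else NA_real_

  dq <- if (!is.na(fnat) && !is.na(irmsd) && !is.na(lrmsd))
    (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
  else NA_real_
  list(fnat = fnat, fnonnat = fnonnat, irmsd = irmsd, lrmsd = lrmsd,
       dockq = dq, n_ref_contacts = nrow(rc), receptor = rec)
}

#' Aggregate per-interface DockQ scores
#'
#' @param per_interface list of [dockq()] results (or a data frame with
#'   columns `dockq` and `n_ref_contacts`).
#' @return list `dockq_ave` (unweighted mean) and `dockq_wave`
#'   (contact-count-weighted mean).
#' @export
dockq_aggregate <- function(per_interface) {
  if (is.data.frame(per_interface)) {
    sc <- per_interface$dockq; w <- per_interface$n_ref_contacts
  } else {
    sc <- vapply(per_interface, function(x) x$dockq %||% NA_real_, 0)
    w <- vapply(per_interface, function(x) x$n_ref_contacts %||% 0, 0)
  }
  ok <- !is.na(sc)
  if (!any(ok))
    return(list(dockq_ave = NA_real_, dockq_wave = NA_real_,
                reason = "no scored interfaces"))
  list(dockq_ave = mean(sc[ok]),
       dockq_wave = sum(sc[ok] * w[ok]) / sum(w[ok]))
}

#' DockQ over all mapped interfaces of a complex
#'
#' Scores every mapped reference chain pair that shares at least one
#' interface contact and aggregates with [dockq_aggregate()].
#'
#' @inheritParams dockq
#' @return list `per_interface`, `dockq_ave`, `dockq_wave`.
#' @export
dockq_all <- function(ref, mdl, mapping, capri_peptide = FALSE,
                      params_aln = alignment_params(),
                      dict = ccd_dictionary()) {
  pairs <- if (is.character(mapping)) mapping else mapping$pairs
  pairs <- pairs[!is.na(pairs)]
  per <- list()
  if (length(pairs) >= 2) {
    cmb <- utils::combn(sort(names(pairs)), 2)
    for (k in seq_len(ncol(cmb))) {
      res <- dockq(ref, mdl, pairs, cmb[, k], capri_peptide, params_aln,
                   dict)
      if (!is.null(res$n_ref_contacts) && res$n_ref_contacts > 0) {
        res$interface <- paste(cmb[, k], collapse = "-")
        per[[length(per) + 1L]] <- res
      }
    }
  }
  c(list(per_interface = per), dockq_aggregate(per))
}
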