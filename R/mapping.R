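#' Chain-mapping search parameters
#'
#' @param exhaustive_limit_qsmap,exhaustive_limit_qsmapr largest problem size
#'   (expressed as a chain count `N`; enumeration is used when the number of
#'   group-respecting mappings does not exceed `N!`) handled exhaustively.
#' @param access_radius accessibility radius (A) between representative
#'   positions for the QS-score greedy search.
#' @param access_contact_radius contact radius (A) for the accessibility
#'   contact-count rule.
#' @param min_interface_contacts minimum inter-residue contacts for a chain
#'   to be considered accessible (QS-score objective).
#' @param msa_columns number of equidistant alignment columns sampled for the
#'   QSMapR backbone-RMSD objective.
#' @param qs_contact_radius interface contact radius of the QS-score (A).
#' @param force_greedy always use the greedy search (testing hook).
#' @return list of class `mapping_params`.
#' @export
mapping_params <- function(exhaustive_limit_qsmap = 8L,
                           exhaustive_limit_qsmapr = 5L,
                           access_radius = 12,
                           access_contact_radius = 8,
                           min_interface_contacts = 3L,
                           msa_columns = 50L,
                           qs_contact_radius = 12,
                           force_greedy = FALSE) {
  structure(as.list(environment()), class = "mapping_params")
}

new_chain_mapping <- function(pairs, objective, objective_value, complete,
                              search_mode, seeds_evaluated = 0L) {
  structure(list(pairs = pairs, objective = objective,
                 objective_value = objective_value, complete = complete,
                 search_mode = search_mode,
                 seeds_evaluated = seeds_evaluated),
            class = "chain_mapping")
}

#' @export
print.chain_mapping <- function(x, ...) {
  cat(sprintf("<chain_mapping> %s = %.4f (%s, %s)\n", x$objective,
              x$objective_value, x$search_mode,
              if (x$complete) "complete" else "incomplete"))
  if (length(x$pairs))
    cat(" ", paste(names(x$pairs), x$pairs, sep = "->", collapse = " "), "\n")
  invisible(x)
}

# ------------------------------------------------------------ search state

#' Prepare a chain-mapping search state
#'
#' Precomputes per-chain-pair score contributions (cached, so exhaustive and
#' greedy searches share them), residue correspondences within groups, and
#' the accessibility matrices used by the greedy extension.
#'
#' @param ref,mdl cleaned structures.
#' @param grouping [assign_model_chains()] result.
#' @param objective `"qs_score"`, `"bb_lddt"` or `"rmsd"`.
#' @param params [mapping_params()]; @param params_aln [alignment_params()].
#' @param dict chemical component dictionary.
#' @param lddt_radius inclusion radius for the `bb_lddt` objective.
#' @return an environment of class `mapping_state`.
#' @export
mapping_search_state <- function(ref, mdl, grouping,
                                 objective = c("qs_score", "bb_lddt", "rmsd"),
                                 params = mapping_params(),
                                 params_aln = alignment_params(),
                                 dict = ccd_dictionary(),
                                 lddt_radius = 15) {
  objective <- match.arg(objective)
  st <- new.env(parent = emptyenv())
  st$objective <- objective
  st$params <- params
  groups <- grouping$groups
  groups <- Filter(function(g) length(g$ref_chains) && length(g$mdl_chains),
                   groups)
  st$groups <- groups
  rch <- sort(unique(unlist(lapply(groups, `[[`, "ref_chains"))))
  mch <- sort(unique(unlist(lapply(groups, `[[`, "mdl_chains"))))
  st$ref_chains <- rch; st$mdl_chains <- mch
  nr <- length(rch); nm <- length(mch)
  st$compat <- matrix(FALSE, nr, nm, dimnames = list(rch, mch))
  st$group_quota <- integer(length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    st$compat[g$ref_chains, g$mdl_chains] <- TRUE
    st$group_quota[gi] <- min(length(g$ref_chains), length(g$mdl_chains))
  }
  st$group_of_ref <- rep(NA_integer_, nr); names(st$group_of_ref) <- rch
  st$group_of_mdl <- rep(NA_integer_, nm); names(st$group_of_mdl) <- mch
  for (gi in seq_along(groups)) {
    st$group_of_ref[groups[[gi]]$ref_chains] <- gi
    st$group_of_mdl[groups[[gi]]$mdl_chains] <- gi
  }
  cache <- new.env(parent = emptyenv())
  st$corr <- list()
  for (r in rch) {
    st$corr[[r]] <- list()
    for (m in mch[st$compat[r, ]]) {
      co <- chain_correspondence(ref, mdl, r, m, params_aln, dict, cache)
      st$corr[[r]][[m]] <- stats::setNames(co$mdl_key, co$ref_key)
    }
  }
  if (objective == "qs_score") {
    build_qs_backend(st, ref, mdl, dict)
  } else if (objective == "bb_lddt") {
    build_lddt_backend(st, ref, mdl, dict, lddt_radius)
  } else {
    build_rmsd_backend(st, ref, mdl, grouping, params, params_aln, dict)
  }
  class(st) <- c("mapping_state", "environment")
  st
}

# contacts per chain pair as plain lists for speed
pair_contact_list <- function(s, chains, dict, radius) {
  rp <- rep_positions(s, dict)
  out <- list()
  n <- length(chains)
  cnt <- matrix(0L, n, n, dimnames = list(chains, chains))
  mind <- matrix(Inf, n, n, dimnames = list(chains, chains))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    p1 <- rp[rp$chain == chains[i], , drop = FALSE]
    p2 <- rp[rp$chain == chains[j], , drop = FALSE]
    if (!nrow(p1) || !nrow(p2)) next
    d <- cross_dist(cbind(p1$x, p1$y, p1$z), cbind(p2$x, p2$y, p2$z))
    mind[i, j] <- mind[j, i] <- min(d)
    hit <- which(d <= radius, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[paste(chains[i], chains[j])]] <-
        list(k1 = p1$key[hit[, 1]], k2 = p2$key[hit[, 2]], d = d[hit])
      cnt[i, j] <- cnt[j, i] <- nrow(hit)
    }
  }
  list(contacts = out, counts = cnt, mindist = mind)
}

build_qs_backend <- function(st, ref, mdl, dict) {
  radius <- st$params$qs_contact_radius
  rch <- st$ref_chains; mch <- st$mdl_chains
  nr <- length(rch); nm <- length(mch)
  R <- pair_contact_list(ref, rch, dict, radius)
  M <- pair_contact_list(mdl, mch, dict, radius)
  # accessibility inputs at 8 A contacts
  R8 <- pair_contact_list(ref, rch, dict, st$params$access_contact_radius)
  M8 <- pair_contact_list(mdl, mch, dict, st$params$access_contact_radius)
  st$acc <- list(ref_mind = R$mindist, mdl_mind = M$mindist,
                 ref_nc = R8$counts, mdl_nc = M8$counts)
  st$NRpair <- R$counts; st$NMpair <- M$counts
  st$NR_total <- sum(R$counts[upper.tri(R$counts)])
  st$NM_total <- sum(M$counts[upper.tri(M$counts)])
  SW <- array(0, c(nr, nr, nm, nm))
  NS <- array(0, c(nr, nr, nm, nm))
  for (i1 in seq_len(nr)) for (i2 in seq_len(nr)) {
    if (i2 <= i1) next
    rc <- R$contacts[[paste(rch[i1], rch[i2])]]
    if (is.null(rc)) next
    for (j1 in which(st$compat[i1, ])) for (j2 in which(st$compat[i2, ])) {
      if (j1 == j2) next
      key <- if (j1 < j2) paste(mch[j1], mch[j2]) else paste(mch[j2], mch[j1])
      mc <- M$contacts[[key]]
      if (is.null(mc)) next
      t1 <- st$corr[[rch[i1]]][[mch[j1]]][rc$k1]
      t2 <- st$corr[[rch[i2]]][[mch[j2]]][rc$k2]
      mid <- if (j1 < j2) paste(mc$k1, mc$k2) else paste(mc$k2, mc$k1)
      hit <- match(paste(t1, t2), mid)
      ok <- !is.na(hit)
      if (!any(ok)) next
      SW[i1, i2, j1, j2] <- sum(pmax(0, 1 - abs(rc$d[ok] -
                                                  mc$d[hit[ok]]) / radius))
      NS[i1, i2, j1, j2] <- sum(ok)
    }
  }
  st$SW <- SW; st$NS <- NS
}

build_lddt_backend <- function(st, ref, mdl, dict, radius) {
  st$lddt_radius <- radius
  thr <- c(0.5, 1, 2, 4)
  rch <- st$ref_chains; mch <- st$mdl_chains
  nr <- length(rch); nm <- length(mch)
  ty_r <- chain_types(ref, dict); ty_m <- chain_types(mdl, dict)
  bb_tab <- function(s, ty) {
    a <- s$atoms
    sel <- a$atom == backbone_rep_atom(ty[a$chain])
    a <- a[sel, , drop = FALSE]
    split(data.frame(key = res_key(a), x = a$x, y = a$y, z = a$z,
                     stringsAsFactors = FALSE), a$chain)
  }
  bbR <- bb_tab(ref, ty_r); bbM <- bb_tab(mdl, ty_m)
  st$mdl_pos <- list()   # model residue key -> coords
  for (m in mch) {
    b <- bbM[[m]]
    st$mdl_pos[[m]] <- if (is.null(b)) NULL else
      stats::setNames(split(cbind(b$x, b$y, b$z), seq_len(nrow(b))), b$key)
  }
  # intra contacts per ref chain; inter per ref chain pair
  intra <- list(); inter <- list()
  TOT_INTRA <- stats::setNames(numeric(nr), rch)
  TOT_INTER <- matrix(0, nr, nr, dimnames = list(rch, rch))
  mindR <- matrix(Inf, nr, nr); mindM <- matrix(Inf, nm, nm)
  for (i in seq_len(nr)) {
    b <- bbR[[rch[i]]]
    if (is.null(b) || nrow(b) < 2) next
    d <- cross_dist(cbind(b$x, b$y, b$z), cbind(b$x, b$y, b$z))
    hit <- which(d <= radius & upper.tri(d), arr.ind = TRUE)
    intra[[rch[i]]] <- list(k1 = b$key[hit[, 1]], k2 = b$key[hit[, 2]],
                            d = d[hit])
    TOT_INTRA[i] <- nrow(hit)
  }
  pairdist <- function(bb, chains, i, j) {
    b1 <- bb[[chains[i]]]; b2 <- bb[[chains[j]]]
    if (is.null(b1) || is.null(b2)) return(NULL)
    cross_dist(cbind(b1$x, b1$y, b1$z), cbind(b2$x, b2$y, b2$z))
  }
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    if (j <= i) next
    d <- pairdist(bbR, rch, i, j)
    if (is.null(d)) next
    mindR[i, j] <- mindR[j, i] <- min(d)
    hit <- which(d <= radius, arr.ind = TRUE)
    if (nrow(hit)) {
      b1 <- bbR[[rch[i]]]; b2 <- bbR[[rch[j]]]
      inter[[paste(rch[i], rch[j])]] <-
        list(k1 = b1$key[hit[, 1]], k2 = b2$key[hit[, 2]], d = d[hit])
      TOT_INTER[i, j] <- nrow(hit)
    }
  }
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (j <= i) next
    d <- pairdist(bbM, mch, i, j)
    if (!is.null(d)) mindM[i, j] <- mindM[j, i] <- min(d)
  }
  st$acc <- list(ref_mind = mindR, mdl_mind = mindM)
  st$TOT_INTRA <- TOT_INTRA; st$TOT_INTER <- TOT_INTER
  st$TOT_ALL <- sum(TOT_INTRA) + sum(TOT_INTER)

  mpos_lookup <- function(m) {
    b <- bbM[[m]]
    if (is.null(b)) return(NULL)
    mm <- cbind(b$x, b$y, b$z); rownames(mm) <- b$key; mm
  }
  mposs <- lapply(stats::setNames(mch, mch), mpos_lookup)
  pres_count <- function(k1, k2, dref, map1, map2, mpos1, mpos2) {
    t1 <- map1[k1]; t2 <- map2[k2]
    ok <- !is.na(t1) & !is.na(t2) & t1 %in% rownames(mpos1) &
      t2 %in% rownames(mpos2)
    if (!any(ok)) return(0)
    dm <- sqrt(rowSums((mpos1[t1[ok], , drop = FALSE] -
                          mpos2[t2[ok], , drop = FALSE])^2))
    dd <- abs(dm - dref[ok])
    sum(vapply(thr, function(t) sum(dd <= t), 0))
  }
  PRES_INTRA <- matrix(0, nr, nm, dimnames = list(rch, mch))
  for (i in seq_len(nr)) {
    ic <- intra[[rch[i]]]
    if (is.null(ic)) next
    for (j in which(st$compat[i, ])) {
      cmap <- st$corr[[rch[i]]][[mch[j]]]
      PRES_INTRA[i, j] <- pres_count(ic$k1, ic$k2, ic$d, cmap, cmap,
                                     mposs[[mch[j]]], mposs[[mch[j]]])
    }
  }
  PRES_INTER <- array(0, c(nr, nr, nm, nm))
  for (i1 in seq_len(nr)) for (i2 in seq_len(nr)) {
    if (i2 <= i1) next
    ic <- inter[[paste(rch[i1], rch[i2])]]
    if (is.null(ic)) next
    for (j1 in which(st$compat[i1, ])) for (j2 in which(st$compat[i2, ])) {
      if (j1 == j2) next
      PRES_INTER[i1, i2, j1, j2] <-
        pres_count(ic$k1, ic$k2, ic$d,
                   st$corr[[rch[i1]]][[mch[j1]]],
                   st$corr[[rch[i2]]][[mch[j2]]],
                   mposs[[mch[j1]]], mposs[[mch[j2]]])
    }
  }
  st$PRES_INTRA <- PRES_INTRA; st$PRES_INTER <- PRES_INTER
}

build_rmsd_backend <- function(st, ref, mdl, grouping, params, params_aln,
                               dict) {
  n_cols <- params$msa_columns
  blocks <- list()
  atom_xyz <- function(s) {
    a <- s$atoms
    k <- paste(res_key(a), a$atom)
    m <- coords(a); rownames(m) <- k; m
  }
  xr <- atom_xyz(ref); xm <- atom_xyz(mdl)
  ty_r <- chain_types(ref, dict)
  for (gi in seq_along(st$groups)) {
    g <- st$groups[[gi]]
    rep_at <- backbone_rep_atom(g$chain_type)
    L <- nchar(g$rep_seq)
    members <- list()
    for (ch in g$ref_chains) members[[paste0("R", ch)]] <-
      list(s = ref, ch = ch, x = xr)
    for (ch in g$mdl_chains) members[[paste0("M", ch)]] <-
      list(s = mdl, ch = ch, x = xm)
    colmap <- list()   # per member: rep position -> residue key or NA
    for (nm2 in names(members)) {
      mb <- members[[nm2]]
      res <- chain_residues(mb$s, mb$ch)
      al <- align_pair(g$rep_seq, extract_sequence(mb$s, mb$ch, dict),
                       g$chain_type, params_aln,
                       num_a = paste(seq_len(L), ""),
                       num_b = paste(res$resno, res$ins))
      v <- rep(NA_character_, L)
      v[al$a_idx] <- res$key[al$b_idx]
      colmap[[nm2]] <- v
    }
    covered <- Reduce(`&`, lapply(colmap, function(v) {
      !is.na(v)
    }))
    # require the representative backbone atom in every member
    for (nm2 in names(members)) {
      mb <- members[[nm2]]
      kk <- paste(colmap[[nm2]], rep_at)
      covered <- covered & kk %in% rownames(mb$x)
    }
    cols <- which(covered)
    if (length(cols) > n_cols)
      cols <- cols[unique(round(seq(1, length(cols), length.out = n_cols)))]
    for (nm2 in names(members)) {
      mb <- members[[nm2]]
      if (!length(cols)) { blocks[[nm2]] <- NULL; next }
      blocks[[nm2]] <- mb$x[paste(colmap[[nm2]][cols], rep_at), ,
                            drop = FALSE]
    }
  }
  st$blocks <- blocks
  st$rmsd_of <- function(pairs) {
    if (!length(pairs)) return(Inf)
    X <- NULL; Y <- NULL
    for (r in names(pairs)) {
      bx <- st$blocks[[paste0("R", r)]]
      by <- st$blocks[[paste0("M", pairs[[r]])]]
      if (is.null(bx) || is.null(by)) next
      X <- rbind(X, bx); Y <- rbind(Y, by)
    }
    if (is.null(X) || nrow(X) < 3) return(Inf)
    kabsch(X, Y)$rmsd
  }
}

# ------------------------------------------------------------ evaluation

# mapping as named character vector ref chain -> model chain (mapped only)
score_mapping <- function(st, pairs) {
  rch <- st$ref_chains; mch <- st$mdl_chains
  if (st$objective == "rmsd") return(st$rmsd_of(pairs))
  ri <- match(names(pairs), rch); mi <- match(unname(pairs), mch)
  if (length(ri) >= 2) {
    cmb <- utils::combn(seq_along(ri), 2)
    a <- cmb[1, ]; b <- cmb[2, ]
    swp <- ri[a] > ri[b]
    i1 <- ifelse(swp, ri[b], ri[a]); i2 <- ifelse(swp, ri[a], ri[b])
    j1 <- ifelse(swp, mi[b], mi[a]); j2 <- ifelse(swp, mi[a], mi[b])
    idx <- cbind(i1, i2, j1, j2)
  } else idx <- NULL
  if (st$objective == "qs_score") {
    num <- if (is.null(idx)) 0 else sum(st$SW[idx])
    ns <- if (is.null(idx)) 0 else sum(st$NS[idx])
    union <- st$NR_total + st$NM_total - ns
    if (union == 0) return(NA_real_)
    num / union
  } else {
    pres <- sum(st$PRES_INTRA[cbind(ri, mi)]) +
      if (is.null(idx)) 0 else sum(st$PRES_INTER[idx])
    if (st$TOT_ALL == 0) return(NA_real_)
    pres / (4 * st$TOT_ALL)
  }
}

better_than <- function(st, a, b) {
  if (is.na(a)) return(FALSE)
  if (is.na(b)) return(TRUE)
  if (st$objective == "rmsd") a < b - 1e-12 else a > b + 1e-12
}

mapping_complete <- function(st, pairs) {
  for (gi in seq_along(st$groups)) {
    g <- st$groups[[gi]]
    if (sum(names(pairs) %in% g$ref_chains) < st$group_quota[gi])
      return(FALSE)
  }
  TRUE
}

count_mappings <- function(grouping) {
  total <- 1
  for (g in grouping$groups) {
    a <- length(g$ref_chains); b <- length(g$mdl_chains)
    if (a == 0 || b == 0) next
    lo <- min(a, b); hi <- max(a, b)
    total <- total * prod(seq(hi - lo + 1, hi))
    if (total > 1e9) return(Inf)
  }
  total
}

enumerate_mappings <- function(st) {
  per_group <- list()
  for (gi in seq_along(st$groups)) {
    g <- st$groups[[gi]]
    R <- g$ref_chains; M <- g$mdl_chains
    if (length(R) <= length(M)) {
      inj <- all_injections(length(R), length(M))
      per_group[[gi]] <- lapply(seq_len(nrow(inj)), function(k)
        stats::setNames(M[inj[k, ]], R))
    } else {
      inj <- all_injections(length(M), length(R))
      per_group[[gi]] <- lapply(seq_len(nrow(inj)), function(k)
        stats::setNames(M, R[inj[k, ]]))
    }
  }
  grids <- do.call(expand.grid, c(lapply(per_group, seq_along),
                                  KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grids)), function(row) {
    out <- character(0)
    for (gi in seq_along(per_group))
      out <- c(out, per_group[[gi]][[grids[row, gi]]])
    out
  })
}

# ------------------------------------------------------------ greedy

# candidate (ref, mdl) index pairs for extending `ps`, as a 2-column
# integer matrix ordered lexicographically by chain ids (deterministic
# tie-breaking); accessibility per the objective's rules
candidate_matrix <- function(st, ps, restrict_access = TRUE) {
  nr <- length(st$ref_chains); nm <- length(st$mdl_chains)
  ref_ok <- rep(TRUE, nr); mdl_ok <- rep(TRUE, nm)
  ref_ok[ps$ri] <- FALSE; mdl_ok[ps$mi] <- FALSE
  full <- which(ps$gcount >= st$group_quota)
  if (length(full))
    ref_ok[st$group_of_ref %in% full] <- FALSE
  if (restrict_access && st$objective != "rmsd" && length(ps$ri)) {
    if (st$objective == "qs_score") {
      ref_ok <- ref_ok & ps$racc_mind <= st$params$access_radius &
        ps$racc_nc >= st$params$min_interface_contacts
      mdl_ok <- mdl_ok & ps$macc_mind <= st$params$access_radius &
        ps$macc_nc >= st$params$min_interface_contacts
    } else {
      ref_ok <- ref_ok & ps$racc_mind <= st$lddt_radius
      mdl_ok <- mdl_ok & ps$macc_mind <= st$lddt_radius + 4
    }
  }
  ok <- st$compat & outer(ref_ok, mdl_ok, `&`)
  hit <- which(ok, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
}

extend_once <- function(st, ps, restrict_access = TRUE) {
  cand <- candidate_matrix(st, ps, restrict_access)
  if (is.null(cand)) return(NULL)
  n <- nrow(cand)
  if (st$objective == "rmsd") {
    sc <- vapply(seq_len(n), function(k)
      st$rmsd_of(c(ps$pairs, stats::setNames(
        st$mdl_chains[cand[k, 2]], st$ref_chains[cand[k, 1]]))), 0)
    best <- which.min(sc)
  } else {
    dnum <- numeric(n); dns <- numeric(n); dpres <- numeric(n)
    if (st$objective == "bb_lddt")
      dpres <- st$PRES_INTRA[cand]
    for (k in seq_along(ps$ri)) {
      rik <- ps$ri[k]; mik <- ps$mi[k]
      swp <- rik > cand[, 1]
      idx <- cbind(ifelse(swp, cand[, 1], rik),
                   ifelse(swp, rik, cand[, 1]),
                   ifelse(swp, cand[, 2], mik),
                   ifelse(swp, mik, cand[, 2]))
      if (st$objective == "qs_score") {
        dnum <- dnum + st$SW[idx]; dns <- dns + st$NS[idx]
      } else dpres <- dpres + st$PRES_INTER[idx]
    }
    sc <- if (st$objective == "qs_score")
      (ps$num + dnum) / pmax(st$NR_total + st$NM_total - (ps$ns + dns), 1e-12)
    else (ps$pres + dpres) / max(4 * st$TOT_ALL, 1e-12)
    best <- which.max(sc)
  }
  list(ps = partial_add(st, ps, st$ref_chains[cand[best, 1]],
                        st$mdl_chains[cand[best, 2]]),
       score = sc[best])
}

# incremental partial-mapping state: score deltas come from the cached
# contribution arrays, so candidate evaluation is O(|mapping|); chain
# accessibility (min distance / contact count to the mapped set) is
# maintained incrementally as well
partial_new <- function(st) {
  nr <- length(st$ref_chains); nm <- length(st$mdl_chains)
  list(pairs = stats::setNames(character(0), character(0)),
       ri = integer(0), mi = integer(0), num = 0, ns = 0, pres = 0,
       gcount = integer(length(st$groups)),
       racc_mind = rep(Inf, nr), macc_mind = rep(Inf, nm),
       racc_nc = numeric(nr), macc_nc = numeric(nm))
}

partial_delta <- function(st, ps, ri0, mi0) {
  if (!length(ps$ri))
    return(list(num = 0, ns = 0,
                pres = if (st$objective == "bb_lddt")
                  st$PRES_INTRA[ri0, mi0] else 0))
  swp <- ps$ri > ri0
  idx <- cbind(ifelse(swp, ri0, ps$ri), ifelse(swp, ps$ri, ri0),
               ifelse(swp, mi0, ps$mi), ifelse(swp, ps$mi, mi0))
  if (st$objective == "qs_score")
    list(num = sum(st$SW[idx]), ns = sum(st$NS[idx]), pres = 0)
  else
    list(num = 0, ns = 0,
         pres = st$PRES_INTRA[ri0, mi0] + sum(st$PRES_INTER[idx]))
}

partial_eval <- function(st, ps, r, m) {
  if (st$objective == "rmsd")
    return(st$rmsd_of(c(ps$pairs, stats::setNames(m, r))))
  ri0 <- match(r, st$ref_chains); mi0 <- match(m, st$mdl_chains)
  d <- partial_delta(st, ps, ri0, mi0)
  if (st$objective == "qs_score") {
    den <- st$NR_total + st$NM_total - (ps$ns + d$ns)
    if (den <= 0) NA_real_ else (ps$num + d$num) / den
  } else {
    if (st$TOT_ALL == 0) NA_real_
    else (ps$pres + d$pres) / (4 * st$TOT_ALL)
  }
}

partial_add <- function(st, ps, r, m) {
  ri0 <- match(r, st$ref_chains); mi0 <- match(m, st$mdl_chains)
  if (st$objective != "rmsd") {
    d <- partial_delta(st, ps, ri0, mi0)
    ps$num <- ps$num + d$num; ps$ns <- ps$ns + d$ns
    ps$pres <- ps$pres + d$pres
    ps$racc_mind <- pmin(ps$racc_mind, st$acc$ref_mind[, ri0])
    ps$macc_mind <- pmin(ps$macc_mind, st$acc$mdl_mind[, mi0])
    if (!is.null(st$acc$ref_nc)) {
      ps$racc_nc <- ps$racc_nc + st$acc$ref_nc[, ri0]
      ps$macc_nc <- ps$macc_nc + st$acc$mdl_nc[, mi0]
    }
  }
  gi <- st$group_of_ref[[r]]
  ps$gcount[gi] <- ps$gcount[gi] + 1L
  ps$pairs <- c(ps$pairs, stats::setNames(m, r))
  ps$ri <- c(ps$ri, ri0); ps$mi <- c(ps$mi, mi0)
  ps
}

partial_score <- function(st, ps) {
  if (st$objective == "rmsd") return(st$rmsd_of(ps$pairs))
  if (st$objective == "qs_score") {
    den <- st$NR_total + st$NM_total - ps$ns
    if (den <= 0) NA_real_ else ps$num / den
  } else {
    if (st$TOT_ALL == 0) NA_real_ else ps$pres / (4 * st$TOT_ALL)
  }
}


#' Greedy mapping extension from an initial chain pair
#'
#' Iteratively adds the accessible reference/model chain pair that most
#' improves the objective; when the extension stalls before the mapping is
#' complete (disconnected complexes), every unmapped pair is tried as a
#' re-seed and the best-scoring continuation is kept, so a full mapping is
#' always returned.
#'
#' @param st [mapping_search_state()].
#' @param ref_chain,mdl_chain the seed pair (must share a chain group).
#' @return list `pairs` (named vector), `score`.
#' @export
greedy_extend <- function(st, ref_chain, mdl_chain) {
  stopifnot(st$compat[ref_chain, mdl_chain])
  run_to_stall <- function(ps) {
    repeat {
      step <- extend_once(st, ps)
      if (is.null(step)) return(ps)
      ps <- step$ps
    }
  }
  ps <- run_to_stall(partial_add(st, partial_new(st), ref_chain, mdl_chain))
  while (!mapping_complete(st, ps$pairs)) {
    cand <- candidate_matrix(st, ps, restrict_access = FALSE)
    if (is.null(cand)) break
    best <- NULL; best_sc <- NA_real_
    for (k in seq_len(nrow(cand))) {
      p2 <- run_to_stall(partial_add(st, ps, st$ref_chains[cand[k, 1]],
                                     st$mdl_chains[cand[k, 2]]))
      sc <- partial_score(st, p2)
      if (is.null(best) || better_than(st, sc, best_sc)) {
        best <- p2; best_sc <- sc
      }
    }
    ps <- best
  }
  list(pairs = ps$pairs, score = score_mapping(st, ps$pairs))
}

search_mapping <- function(st, exhaustive_limit, force_greedy = FALSE) {
  n_total <- count_mappings(list(groups = st$groups))
  use_exhaustive <- !force_greedy && n_total <= factorial(exhaustive_limit)
  if (use_exhaustive) {
    maps <- enumerate_mappings(st)
    best <- NULL; best_sc <- NA_real_
    for (p in maps) {
      sc <- score_mapping(st, p)
      if (is.null(best) || better_than(st, sc, best_sc)) {
        best <- p; best_sc <- sc
      }
    }
    return(list(pairs = best, score = best_sc, mode = "exhaustive",
                seeds = length(maps)))
  }
  seeds <- candidate_matrix(st, partial_new(st), restrict_access = FALSE)
  best <- NULL; best_sc <- NA_real_
  for (k in seq_len(NROW(seeds))) {
    res <- greedy_extend(st, st$ref_chains[seeds[k, 1]],
                         st$mdl_chains[seeds[k, 2]])
    if (is.null(best) || better_than(st, res$score, best_sc)) {
      best <- res$pairs; best_sc <- res$score
    }
  }
  list(pairs = best, score = best_sc, mode = "greedy",
       seeds = NROW(seeds))
}

# ------------------------------------------------------------ public API

#' QSMap: chain mapping optimising QS-score (or backbone LDDT)
#'
#' Optimises the interface-contact QS-score; switches to backbone LDDT
#' (CA/C3' representatives) with a 30 A inclusion radius when nucleotide
#' chains are involved. Problems whose group-respecting mapping count does
#' not exceed `exhaustive_limit_qsmap!` are enumerated exhaustively;
#' larger problems use the greedy extension seeded from every compatible
#' reference/model chain pair.
#'
#' @param ref,mdl cleaned structures.
#' @param grouping [assign_model_chains()] result.
#' @param params [mapping_params()]; @param params_aln [alignment_params()].
#' @param dict chemical component dictionary.
#' @return a `chain_mapping`.
#' @export
qsmap <- function(ref, mdl, grouping, params = mapping_params(),
                  params_aln = alignment_params(), dict = ccd_dictionary()) {
  has_nuc <- any(vapply(grouping$groups, function(g)
    g$chain_type == "nucleotide", TRUE))
  objective <- if (isTRUE(has_nuc)) "bb_lddt" else "qs_score"
  st <- mapping_search_state(ref, mdl, grouping, objective, params,
                             params_aln, dict,
                             lddt_radius = if (isTRUE(has_nuc)) 30 else 15)
  if (!length(st$ref_chains) || !length(st$mdl_chains)) {
    warning("no mappable chains")
    return(new_chain_mapping(character(0), objective, NA_real_, FALSE,
                             "none"))
  }
  res <- search_mapping(st, params$exhaustive_limit_qsmap,
                        params$force_greedy)
  new_chain_mapping(res$pairs, objective, res$score,
                    mapping_complete(st, res$pairs), res$mode, res$seeds)
}

#' QSMapR: chain mapping optimising backbone RMSD
#'
#' For each chain group a multiple alignment to the group representative
#' defines shared columns; `msa_columns` equidistant columns covered in every
#' member chain supply CA (C3') positions. Candidate mappings are scored by
#' the Kabsch-minimal RMSD over the stacked positions; enumeration is used
#' for small problems, the greedy extension otherwise.
#'
#' @inheritParams qsmap
#' @return a `chain_mapping` with objective `"rmsd"`.
#' @export
qsmapr <- function(ref, mdl, grouping, params = mapping_params(),
                   params_aln = alignment_params(),
                   dict = ccd_dictionary()) {
  st <- mapping_search_state(ref, mdl, grouping, "rmsd", params,
                             params_aln, dict)
  if (!length(st$ref_chains) || !length(st$mdl_chains)) {
    warning("no mappable chains")
    return(new_chain_mapping(character(0), "rmsd", NA_real_, FALSE, "none"))
  }
  res <- search_mapping(st, params$exhaustive_limit_qsmapr,
                        params$force_greedy)
  new_chain_mapping(res$pairs, "rmsd", res$score,
                    mapping_complete(st, res$pairs), res$mode, res$seeds)
}
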