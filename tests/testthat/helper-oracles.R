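# Independent oracles: deliberately simple re-implementations used to
# cross-check the optimised engines. They assume fixture conventions
# (identical sequences and numbering between reference and model), so the
# residue correspondence is by residue number, not by alignment.

oracle_rep_positions <- function(s) {
  a <- s$atoms
  want <- ifelse(a$resid %in% c("A", "C", "G", "U", "DA", "DC", "DG", "DT"),
                 "C3'", ifelse(a$resid == "GLY", "CA", "CB"))
  a <- a[a$atom == want, , drop = FALSE]
  list(chain = a$chain, resno = a$resno, xyz = cbind(a$x, a$y, a$z))
}

# naive QS-score for a given chain mapping (named vector ref -> mdl):
# contacts = rep positions < 12 A across chains; shared weight
# max(0, 1 - |dr - dm|/12); global = sum(w) / union count
oracle_qs <- function(ref, mdl, pairs) {
  rp <- oracle_rep_positions(ref)
  mp <- oracle_rep_positions(mdl)
  contacts <- function(p) {
    d <- as.matrix(dist(p$xyz))
    hit <- which(d <= 12 & upper.tri(d) &
                   outer(p$chain, p$chain, `!=`), arr.ind = TRUE)
    data.frame(c1 = p$chain[hit[, 1]], r1 = p$resno[hit[, 1]],
               c2 = p$chain[hit[, 2]], r2 = p$resno[hit[, 2]],
               d = d[hit], stringsAsFactors = FALSE)
  }
  rc <- contacts(rp)
  mc <- contacts(mp)
  m2r <- stats::setNames(names(pairs), unname(pairs))
  mc$c1 <- m2r[mc$c1]; mc$c2 <- m2r[mc$c2]
  id <- function(x) {
    a <- paste(x$c1, x$r1); b <- paste(x$c2, x$r2)
    ifelse(a < b, paste(a, b), paste(b, a))
  }
  rid <- id(rc); mid <- id(mc)
  hit <- match(rid, mid)
  w <- ifelse(is.na(hit), 0, pmax(0, 1 - abs(rc$d - mc$d[hit]) / 12))
  union_n <- nrow(rc) + sum(is.na(match(mid, rid)))
  if (union_n == 0) return(NA_real_)
  sum(w) / union_n
}

# naive backbone RMSD for a chain mapping: CA/C3' atoms paired by residue
# number, minimal RMSD written out directly from the SVD closed form
oracle_rmsd <- function(ref, mdl, pairs) {
  rep_xyz <- function(s, ch) {
    a <- s$atoms[s$atoms$chain == ch & s$atoms$atom %in% c("CA", "C3'"), ,
                 drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    cbind(a$x, a$y, a$z)
  }
  X <- NULL; Y <- NULL
  for (r in names(pairs)) {
    X <- rbind(X, rep_xyz(ref, r))
    Y <- rbind(Y, rep_xyz(mdl, pairs[[r]]))
  }
  X0 <- scale(X, scale = FALSE)
  Y0 <- scale(Y, scale = FALSE)
  s <- svd(t(Y0) %*% X0)
  rot <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  sqrt(mean(rowSums((Y0 %*% t(rot) - X0)^2)))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
  }))
}

# brute-force optimum over all chain permutations of a homo-oligomer
oracle_best_mapping <- function(ref, mdl, objective = c("qs", "rmsd")) {
  objective <- match.arg(objective)
  chains <- sort(unique(ref$atoms$chain))
  mchains <- sort(unique(mdl$atoms$chain))
  perms <- all_perms(length(chains))
  best <- if (objective == "qs") -Inf else Inf
  for (k in seq_len(nrow(perms))) {
    pairs <- stats::setNames(mchains[perms[k, ]], chains)
    v <- if (objective == "qs") oracle_qs(ref, mdl, pairs)
         else oracle_rmsd(ref, mdl, pairs)
    if (is.na(v)) next
    if (objective == "qs") best <- max(best, v) else best <- min(best, v)
  }
  best
}

# naive double-loop LDDT: per reference atom i, distances to atoms j > i
# within the radius (excluding same-residue pairs), model distances by
# (chain, resno, atom name) lookup; counts per threshold
oracle_lddt_counts <- function(ref, mdl, pairs, radius = 15,
                               variant = "full",
                               thresholds = c(0.5, 1, 2, 4)) {
  nuc <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")
  a <- ref$atoms[ref$atoms$elem != "H", , drop = FALSE]
  if (variant == "backbone") {
    want <- ifelse(a$resid %in% nuc, "C3'", "CA")
    a <- a[a$atom == want, , drop = FALSE]
  }
  ma <- mdl$atoms
  mkey <- paste(ma$chain, ma$resno, ma$atom)
  midx <- match(paste(pairs[a$chain], a$resno, a$atom), mkey)
  axyz <- cbind(a$x, a$y, a$z)
  mxyz <- cbind(ma$x, ma$y, ma$z)
  total <- 0L
  preserved <- stats::setNames(integer(length(thresholds)),
                               as.character(thresholds))
  n <- nrow(a)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    dr <- sqrt(colSums((t(axyz[j, , drop = FALSE]) - axyz[i, ])^2))
    keep <- dr <= radius &
      !(a$chain[j] == a$chain[i] & a$resno[j] == a$resno[i])
    if (variant == "interface") keep <- keep & a$chain[j] != a$chain[i]
    j <- j[keep]; dr <- dr[keep]
    if (!length(j)) next
    total <- total + length(j)
    mi <- midx[i]; mj <- midx[j]
    ok <- !is.na(mi) & !is.na(mj)
    if (!any(ok)) next
    dm <- sqrt(colSums((t(mxyz[mj[ok], , drop = FALSE]) - mxyz[mi, ])^2))
    dd <- abs(dm - dr[ok])
    for (t in thresholds)
      preserved[as.character(t)] <-
        preserved[as.character(t)] + sum(dd <= t)
  }
  list(total = total, preserved = preserved)
}

# reorder the atoms of a ligand (bond indices remapped accordingly)
permute_ligand <- function(lig, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  lig$atoms <- lig$atoms[perm, , drop = FALSE]
  rownames(lig$atoms) <- NULL
  lig$bonds$a1 <- inv[lig$bonds$a1]
  lig$bonds$a2 <- inv[lig$bonds$a2]
  lig
}

# shorthand: cleaned ref/model pair from make_complex output
cleaned <- function(fx, replace_nonstandard = TRUE) {
  list(ref = cleanup_polymer(fx$ref, replace_nonstandard = replace_nonstandard),
       mdl = cleanup_polymer(fx$model, replace_nonstandard = replace_nonstandard))
}

identity_mapping <- function(s) {
  ch <- sort(unique(s$atoms$chain))
  stats::setNames(ch, ch)
}
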