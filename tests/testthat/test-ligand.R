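lig_fixture <- function(seed = 80, shift = 0, template = "ring", ...) {
  fx <- make_complex(c(A = 2), chain_length = 16, seed = seed,
                     ligand = template, ligand_shift = shift, ...)
  cl <- cleaned(fx, replace_nonstandard = FALSE)
  list(ref = cl$ref, mdl = cl$mdl,
       rl = fx$ref$ligands[[1]], ml = fx$model$ligands[[1]])
}

test_that("graph matching enumerates symmetries and respects elements", {
  ring <- make_ligand("ring")
  m <- match_ligands(ring, ring)
  expect_length(m$correspondences, 12)      # C6 ring automorphisms
  expect_equal(m$coverage, 1.0)
  lin <- make_ligand("linear")
  expect_length(match_ligands(lin, lin)$correspondences, 2)
  expect_null(match_ligands(ring, lin))     # different atom counts
  # element labels matter: C-C-O vs C-C-C
  cco <- qsbench:::new_ligand("cco",
    data.frame(atom = c("C1", "C2", "O1"), elem = c("C", "C", "O"),
               x = 0:2 * 1.4, y = 0, z = 0),
    data.frame(a1 = 1:2, a2 = 2:3, order = 1L))
  ccc <- qsbench:::new_ligand("ccc",
    data.frame(atom = c("C1", "C2", "C3"), elem = c("C", "C", "C"),
               x = 0:2 * 1.4, y = 0, z = 0),
    data.frame(a1 = 1:2, a2 = 2:3, order = 1L))
  expect_null(match_ligands(cco, ccc))
  # subgraph: reference missing atoms matches with partial coverage
  part <- lin
  part$atoms <- part$atoms[1:2, ]
  part$bonds <- part$bonds[1, , drop = FALSE]
  expect_null(match_ligands(part, lin))       # off by default
  ms <- match_ligands(part, lin, allow_subgraph = TRUE)
  expect_equal(ms$coverage, 0.5)
  expect_true(ms$subgraph_mode)
  # model smaller than reference never matches (completeness rule)
  expect_null(match_ligands(lin, part, allow_subgraph = TRUE))
})

test_that("binding site detection applies the 4 A rule strictly", {
  rows <- do.call(rbind, lapply(1:8, function(i) data.frame(
    chain = "A", resno = i, ins = "", resid = "ALA", atom = "CA",
    elem = "C", x = i * 10, y = 0, z = 0, occ = 1, het = FALSE)))
  s <- qsbench:::new_struct(rows)
  lg <- make_ligand("ion")
  lg$atoms$x <- 10 + 3.9; lg$atoms$y <- 0; lg$atoms$z <- 0
  site <- detect_binding_site(s, lg)
  expect_equal(site$residues, "A|1|")
  lg$atoms$x <- 10 + 4.1
  expect_length(detect_binding_site(s, lg)$residues, 0)
  # raising the radius recovers the site
  expect_length(detect_binding_site(s, lg, radius = 5)$residues, 1)
})

test_that("BiSyRMSD is exact on identity and redock shifts", {
  z <- lig_fixture(seed = 81)
  m <- match_ligands(z$rl, z$rl)
  r0 <- bisy_rmsd(z$ref, z$ref, z$rl, z$rl, m)
  expect_equal(r0$bisy_rmsd, 0, tolerance = 1e-9)
  expect_equal(r0$rmsd_lp, 0, tolerance = 1e-9)
  expect_equal(r0$lddt_lp, 1.0)
  # identical receptor frames: superposition is the identity, so the
  # symmetry-corrected RMSD equals the applied shift
  z2 <- lig_fixture(seed = 81, shift = 1.3)
  r <- bisy_rmsd(z2$ref, z2$mdl, z2$rl, z2$ml, match_ligands(z2$rl, z2$ml))
  expect_equal(r$bisy_rmsd, 1.3, tolerance = 1e-9)
})

test_that("symmetry correction absorbs a ring flip exactly", {
  z <- lig_fixture(seed = 82)
  ml <- z$rl
  ctr <- colMeans(as.matrix(ml$atoms[, c("x", "y", "z")]))
  R <- qsbench:::rotation_about(c(1, 0, 0), pi)
  xyz <- sweep(sweep(as.matrix(ml$atoms[, c("x", "y", "z")]), 2, ctr) %*%
                 t(R), 2, ctr, `+`)
  ml$atoms$x <- xyz[, 1]; ml$atoms$y <- xyz[, 2]; ml$atoms$z <- xyz[, 3]
  m <- match_ligands(z$rl, ml)
  r <- bisy_rmsd(z$ref, z$ref, z$rl, ml, m)
  expect_equal(r$bisy_rmsd, 0, tolerance = 1e-9)
  naive <- rmsd_nofit(as.matrix(z$rl$atoms[, c("x", "y", "z")]), xyz)
  expect_gt(naive, 1)
})

test_that("ligand scores are invariant under atom input order", {
  z <- lig_fixture(seed = 83, shift = 0.9)
  m0 <- match_ligands(z$rl, z$ml)
  base_b <- bisy_rmsd(z$ref, z$mdl, z$rl, z$ml, m0)$bisy_rmsd
  base_p <- lddt_pli(z$ref, z$mdl, z$rl, z$ml, m0)$lddt_pli
  set.seed(84)
  for (k in 1:5) {
    perm <- sample(nrow(z$ml$atoms))
    mlp <- permute_ligand(z$ml, perm)
    m <- match_ligands(z$rl, mlp)
    expect_equal(bisy_rmsd(z$ref, z$mdl, z$rl, mlp, m)$bisy_rmsd, base_b,
                 tolerance = 1e-9)
    expect_equal(lddt_pli(z$ref, z$mdl, z$rl, mlp, m)$lddt_pli, base_p,
                 tolerance = 1e-9)
  }
})

test_that("BiSyRMSD equals a brute-force mapping x symmetry minimum", {
  fx <- make_complex(c(A = 2), chain_length = 12, seed = 85,
                     ligand = "ring", ligand_shift = 0.7, noise = 0.2,
                     relabel = "cycle")
  cl <- cleaned(fx, replace_nonstandard = FALSE)
  rl <- fx$ref$ligands[[1]]; ml <- fx$model$ligands[[1]]
  m <- match_ligands(rl, ml)
  r <- bisy_rmsd(cl$ref, cl$mdl, rl, ml, m)
  # oracle: both chain assignments x all 12 correspondences
  site <- detect_binding_site(cl$ref, rl)
  best <- Inf
  for (mp in list(c(A = "A", B = "B"), c(A = "B", B = "A"))) {
    X <- NULL; Y <- NULL
    for (rch in names(mp)) {
      keys <- site$residues[startsWith(site$residues, paste0(rch, "|"))]
      if (!length(keys)) next
      ra <- cl$ref$atoms
      sel <- paste(ra$chain, ra$resno, ra$ins, sep = "|") %in% keys &
        ra$atom == "CA"
      rsub <- ra[sel, ]
      ma <- cl$mdl$atoms
      mi <- match(paste(mp[[rch]], rsub$resno, "CA"),
                  paste(ma$chain, ma$resno, ma$atom))
      X <- rbind(X, as.matrix(rsub[, c("x", "y", "z")]))
      Y <- rbind(Y, as.matrix(ma[mi, c("x", "y", "z")]))
    }
    if (is.null(X) || nrow(X) < 3) next
    fit <- kabsch(X, Y)
    mt <- fit$transform(as.matrix(ml$atoms[, c("x", "y", "z")]))
    for (cr in m$correspondences)
      best <- min(best, rmsd_nofit(as.matrix(rl$atoms[, c("x", "y", "z")]),
                                   mt[cr, , drop = FALSE]))
  }
  expect_equal(r$bisy_rmsd, best, tolerance = 1e-9)
})

test_that("empty polymer site makes BiSyRMSD not computable", {
  z <- lig_fixture(seed = 86)
  ion <- make_ligand("ion")
  # ion far away from every chain
  ion$atoms$x <- 500
  r <- bisy_rmsd(z$ref, z$mdl, ion, ion, match_ligands(ion, ion))
  expect_true(is.na(r$value))
  expect_match(r$reason, "site")
})

test_that("LDDT-PLI is 1 on identity and penalises added contacts", {
  # trimer whose chain C sits far from the binding site in the reference;
  # the model moves its copy of C right through the site, so the added
  # contacts are mappable (via the equivalent reference chain) and penalised
  fx <- make_complex(c(A = 3), chain_length = 16, seed = 87,
                     ligand = "ring")
  ref <- cleanup_polymer(fx$ref, replace_nonstandard = FALSE)
  rl <- fx$ref$ligands[[1]]
  m <- match_ligands(rl, rl)
  expect_equal(lddt_pli(ref, ref, rl, rl, m)$lddt_pli, 1.0,
               tolerance = 1e-9)
  mdl2 <- ref
  com <- colMeans(as.matrix(rl$atoms[, c("x", "y", "z")]))
  sel <- mdl2$atoms$chain == "C"
  ctr <- colMeans(as.matrix(mdl2$atoms[sel, c("x", "y", "z")]))
  mdl2$atoms$x[sel] <- mdl2$atoms$x[sel] + (com[1] - ctr[1])
  mdl2$atoms$y[sel] <- mdl2$atoms$y[sel] + (com[2] - ctr[2])
  mdl2$atoms$z[sel] <- mdl2$atoms$z[sel] + (com[3] - ctr[3])
  r2 <- lddt_pli(ref, mdl2, rl, rl, m)
  expect_lt(r2$lddt_pli, 1.0)
  # deleting the offending chain restores the score
  mdl3 <- mdl2
  mdl3$atoms <- mdl3$atoms[mdl3$atoms$chain != "C", ]
  r3 <- lddt_pli(ref, mdl3, rl, rl, m)
  expect_gt(r3$lddt_pli, r2$lddt_pli)
})

test_that("translation ladder: BiSyRMSD nondecreasing, LDDT-PLI nonincreasing", {
  vals_b <- c(); vals_p <- c()
  for (shift in c(0, 1, 2.5, 5, 10)) {
    z <- lig_fixture(seed = 88, shift = shift)
    m <- match_ligands(z$rl, z$ml)
    vals_b <- c(vals_b, bisy_rmsd(z$ref, z$mdl, z$rl, z$ml, m)$bisy_rmsd)
    p <- lddt_pli(z$ref, z$mdl, z$rl, z$ml, m)
    vals_p <- c(vals_p, if (is.null(p$lddt_pli)) 0 else p$lddt_pli)
  }
  expect_true(all(diff(vals_b) >= -1e-9))
  expect_true(all(diff(vals_p) <= 1e-9))
})

test_that("disconnected ligand fragments: large BiSyRMSD, nonzero LDDT-PLI", {
  z <- lig_fixture(seed = 89, template = "fragments")
  ml <- z$ml
  # displace the second fragment far away in the model
  ml$atoms$x[3:4] <- ml$atoms$x[3:4] + 100
  m <- match_ligands(z$rl, ml)
  b <- bisy_rmsd(z$ref, z$mdl, z$rl, ml, m)
  p <- lddt_pli(z$ref, z$mdl, z$rl, ml, m)
  expect_gt(b$bisy_rmsd, 20)
  expect_gt(p$lddt_pli, 0)
})

test_that("greedy assignment honours the coverage window and one-to-one", {
  tab <- data.frame(
    ref = c("solvent", "cofactor"), mdl = c("lig1", "lig1"),
    score = c(0.2, 1.5), coverage = c(0.2, 1.0),
    stringsAsFactors = FALSE)
  a <- assign_ligands(tab, "min")
  expect_equal(a$pairs$ref, "cofactor")  # solvent excluded by coverage
  expect_true("solvent" %in% a$unassigned_ref)

  # one-to-one with two copies: better score wins, other stays unassigned
  tab2 <- data.frame(ref = c("r1", "r1"), mdl = c("m1", "m2"),
                     score = c(0.4, 0.1), coverage = 1)
  a2 <- assign_ligands(tab2, "min")
  expect_equal(nrow(a2$pairs), 1)
  expect_equal(a2$pairs$mdl, "m2")
  expect_true("m1" %in% a2$unassigned_mdl)

  # greedy consistency: removing the first assigned pair reproduces the rest
  tab3 <- data.frame(ref = rep(c("r1", "r2"), each = 2),
                     mdl = rep(c("m1", "m2"), 2),
                     score = c(0.1, 0.6, 0.5, 0.2), coverage = 1)
  a3 <- assign_ligands(tab3, "min")
  first <- a3$pairs[1, ]
  rest <- assign_ligands(tab3[!(tab3$ref == first$ref |
                                  tab3$mdl == first$mdl), ], "min")
  expect_equal(a3$pairs[-1, c("ref", "mdl")], rest$pairs[, c("ref", "mdl")],
               ignore_attr = TRUE)
  # max objective picks the highest score
  a4 <- assign_ligands(tab3, "max")
  expect_equal(a4$pairs$score[1], 0.6)
})
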