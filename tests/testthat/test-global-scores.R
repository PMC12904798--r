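test_that("QS-score is 1 on identity, symmetric, and best >= global", {
  fx <- make_complex(c(A = 2, B = 1), chain_length = c(14, 12), seed = 60,
                     noise = 0.4)
  cl <- cleaned(fx)
  mp <- identity_mapping(cl$ref)
  self <- qs_score(cl$ref, cl$ref, mp)
  expect_equal(self$qs_global, 1.0, tolerance = 1e-9)
  expect_equal(self$qs_best, 1.0, tolerance = 1e-9)
  r <- qs_score(cl$ref, cl$mdl, mp)
  rs <- qs_score(cl$mdl, cl$ref, stats::setNames(names(mp), mp))
  expect_equal(r$qs_global, rs$qs_global, tolerance = 1e-9)
  expect_gte(r$qs_best, r$qs_global - 1e-12)
})

test_that("wrong stoichiometry penalises qs_global but not qs_best", {
  dimer <- make_complex(c(A = 2), chain_length = 12, seed = 61)
  tetra <- make_complex(c(A = 4), chain_length = 12, seed = 61)
  ref <- cleanup_polymer(dimer$ref)
  mdl <- cleanup_polymer(tetra$ref)
  grouping <- assign_model_chains(mdl, group_reference_chains(ref))
  m <- qsmap(ref, mdl, grouping)
  r <- qs_score(ref, mdl, m)
  expect_lt(r$qs_global, 1.0)
  expect_gt(r$qs_best, r$qs_global)
})

test_that("monomers have no interface contacts: QS not computable", {
  fx <- make_complex(c(A = 1), chain_length = 12, seed = 62)
  ref <- cleanup_polymer(fx$ref)
  r <- qs_score(ref, ref, c(A = "A"))
  expect_true(is.na(r$qs_global))
  expect_match(r$reason, "interface")
})

test_that("ICS follows F1 arithmetic on a constructed contact fixture", {
  # chains A and B as parallel CA strands 4 A apart: one contact per
  # residue pair (i, i); model displaces half of chain B far away
  mk <- function(move_half) {
    rows <- list()
    for (ch in c("A", "B")) for (i in 1:12) {
      y <- if (ch == "A") 0 else 4
      if (move_half && ch == "B" && i > 6) y <- 200
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno = i, ins = "", resid = "ALA", atom = "CA",
        elem = "C", x = i * 8, y = y, z = 0, occ = 1, het = FALSE,
        stringsAsFactors = FALSE)
    }
    qsbench:::new_struct(do.call(rbind, rows))
  }
  ref <- mk(FALSE); mdl <- mk(TRUE)
  mp <- c(A = "A", B = "B")
  r <- ics_ips(ref, mdl, mp)
  expect_equal(r$ics, 2 / 3, tolerance = 1e-12)   # precision 1, recall 0.5
  # identical structures
  r0 <- ics_ips(ref, ref, mp)
  expect_equal(r0$ics, 1.0)
  expect_equal(r0$ips, 1.0)
})

test_that("trimming removes model-only regions before contact collection", {
  fx <- make_complex(c(A = 2), chain_length = 20, seed = 63, noise = 0.2)
  cl <- cleaned(fx)
  # reference truncated: drop last 8 residues of chain B; the model keeps
  # them (extra region with contacts absent from the reference)
  ref <- cl$ref
  ref$atoms <- ref$atoms[!(ref$atoms$chain == "B" & ref$atoms$resno > 12), ]
  mp <- identity_mapping(ref)
  rt <- ics_ips(ref, cl$mdl, mp, trimmed = TRUE)
  ru <- ics_ips(ref, cl$mdl, mp, trimmed = FALSE)
  expect_gte(rt$ics, ru$ics - 1e-12)
  # and QS-best does not penalise the incomplete reference either
  q <- qs_score(ref, cl$mdl, mp)
  expect_gte(q$qs_best, q$qs_global - 1e-12)
})

test_that("DockQ components and combination behave as defined", {
  fx <- make_complex(c(A = 2), chain_length = 16, seed = 64)
  cl <- cleaned(fx)
  mp <- identity_mapping(cl$ref)
  r <- dockq(cl$ref, cl$ref, mp, c("A", "B"))
  expect_equal(r$fnat, 1.0)
  expect_equal(r$irmsd, 0.0, tolerance = 1e-9)
  expect_equal(r$lrmsd, 0.0, tolerance = 1e-9)
  expect_equal(r$dockq, 1.0, tolerance = 1e-9)
  # displaced ligand chain: fnat 0, DockQ at its RMSD-driven floor
  far <- cl$ref
  sel <- far$atoms$chain == "B"
  far$atoms$x[sel] <- far$atoms$x[sel] + 150
  rf <- dockq(cl$ref, far, mp, c("A", "B"))
  expect_equal(rf$fnat, 0.0)
  floor_val <- (0 + 1 / (1 + (rf$irmsd / 1.5)^2) +
                  1 / (1 + (rf$lrmsd / 8.5)^2)) / 3
  expect_equal(rf$dockq, floor_val, tolerance = 1e-12)
  # internal consistency on a perturbed model
  fx2 <- make_complex(c(A = 2), chain_length = 16, seed = 65, noise = 0.5)
  cl2 <- cleaned(fx2)
  r2 <- dockq(cl2$ref, cl2$mdl, mp, c("A", "B"))
  expect_equal(r2$dockq,
               (r2$fnat + 1 / (1 + (r2$irmsd / 1.5)^2) +
                  1 / (1 + (r2$lrmsd / 8.5)^2)) / 3, tolerance = 1e-12)
  # capri_peptide changes the parameterisation
  r3 <- dockq(cl2$ref, cl2$mdl, mp, c("A", "B"), capri_peptide = TRUE)
  expect_false(isTRUE(all.equal(r2$fnat, r3$fnat)) &&
                 isTRUE(all.equal(r2$irmsd, r3$irmsd)))
})

test_that("DockQ aggregation: ave is unweighted, wave weights by contacts", {
  per <- list(list(dockq = 1.0, n_ref_contacts = 90),
              list(dockq = 0.0, n_ref_contacts = 10))
  agg <- dockq_aggregate(per)
  expect_equal(agg$dockq_ave, 0.5, tolerance = 1e-12)
  expect_equal(agg$dockq_wave, 0.9, tolerance = 1e-12)
  one <- dockq_aggregate(list(list(dockq = 0.7, n_ref_contacts = 5)))
  expect_equal(one$dockq_ave, 0.7)
  expect_equal(one$dockq_wave, 0.7)
  eq <- dockq_aggregate(list(list(dockq = 0.4, n_ref_contacts = 3),
                             list(dockq = 0.4, n_ref_contacts = 70)))
  expect_equal(eq$dockq_ave, eq$dockq_wave)
  expect_true(is.na(dockq_aggregate(list())$dockq_ave))
})

test_that("GDT: identity is 1, half displacement gives exactly 0.5", {
  fx <- make_complex(c(A = 1), chain_length = 40, seed = 66)
  ref <- cleanup_polymer(fx$ref)
  mp <- c(A = "A")
  g0 <- gdt(ref, ref, mp)
  expect_equal(g0$gdt_ts, 1.0)
  expect_equal(g0$gdt_ha, 1.0)
  half <- ref
  sel <- half$atoms$resno > 20
  half$atoms$x[sel] <- half$atoms$x[sel] + 100
  g <- gdt(ref, half, mp)
  expect_equal(unname(g$fractions), rep(0.5, 5), tolerance = 1e-12)
  expect_equal(g$gdt_ts, 0.5, tolerance = 1e-12)
  # nested thresholds are monotone on noisy models
  fx2 <- make_complex(c(A = 1), chain_length = 30, seed = 67, noise = 1.2)
  cl2 <- cleaned(fx2)
  g2 <- gdt(cl2$ref, cl2$mdl, mp)
  expect_true(all(diff(g2$fractions) >= -1e-12))
})

test_that("GDT penalises incomplete models through its denominator", {
  fx <- make_complex(c(A = 1), chain_length = 30, seed = 68)
  ref <- cleanup_polymer(fx$ref)
  part <- ref
  part$atoms <- part$atoms[part$atoms$resno <= 15, ]
  g <- gdt(ref, part, c(A = "A"))
  expect_equal(g$gdt_ts, 0.5, tolerance = 1e-9)
})

test_that("backbone RMSD: zero under rigid motion, bounded displacement", {
  fx <- make_complex(c(A = 2), chain_length = 14, seed = 69,
                     global_rot = 50)
  cl <- cleaned(fx)
  gp <- assign_model_chains(cl$mdl, group_reference_chains(cl$ref))
  mr <- qsmapr(cl$ref, cl$mdl, gp)
  expect_equal(backbone_rmsd(cl$ref, cl$mdl, mr), 0.0, tolerance = 1e-7)
  # one displaced position out of n contributes at most d/sqrt(n)
  ref <- cl$ref
  n <- sum(ref$atoms$atom == "CA")
  one <- ref
  i <- which(one$atoms$atom == "CA")[1]
  d <- 6
  one$atoms$x[i] <- one$atoms$x[i] + d
  r <- backbone_rmsd(ref, one, identity_mapping(ref))
  expect_lte(r, d / sqrt(n) + 1e-9)
  expect_gt(r, 0)
  # degenerate input (fewer than 3 mapped positions) errors
  tiny <- ref
  tiny$atoms <- tiny$atoms[tiny$atoms$resno <= 2 & tiny$atoms$chain == "A", ]
  expect_error(backbone_rmsd(ref, tiny, identity_mapping(ref)), "fewer")
})

test_that("Kabsch fit matches an independent superposition", {
  fx <- make_complex(c(A = 1), chain_length = 20, seed = 70, noise = 1.0)
  cl <- cleaned(fx)
  ours <- backbone_rmsd(cl$ref, cl$mdl, c(A = "A"))
  theirs <- oracle_rmsd(cl$ref, cl$mdl, c(A = "A"))
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})
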