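# a chain of single-CA "islands": pairs of residues a fixed distance apart,
# islands separated far beyond the inclusion radius, so every island
# contributes exactly one contact whose distance we control exactly
island_chain <- function(n_islands, d_ref, d_mdl) {
  mk <- function(d) {
    rows <- list()
    for (i in seq_len(n_islands)) {
      x0 <- (i - 1) * 100
      for (j in 1:2) rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = 2 * (i - 1) + j, ins = "", resid = "ALA",
        atom = "CA", elem = "C", x = x0 + (j - 1) * d, y = 0, z = 0,
        occ = 1, het = FALSE, stringsAsFactors = FALSE)
    }
    qsbench:::new_struct(do.call(rbind, rows))
  }
  list(ref = mk(d_ref), mdl = mk(d_mdl))
}

test_that("uniform 0.7 A distance perturbation gives LDDT exactly 0.75", {
  s <- island_chain(10, 3.0, 3.7)
  tab <- build_contact_table(s$ref)
  expect_equal(length(tab$i), 10)
  r <- lddt(s$mdl, tab, c(A = "A"), s$ref)
  expect_equal(unname(r$fractions), c(0, 1, 1, 1))
  expect_equal(r$score, 0.75, tolerance = 1e-12)
})

test_that("contact tables respect radius, variants and residue exclusion", {
  s <- island_chain(2, 14.9, 14.9)
  tab <- build_contact_table(s$ref, lddt_params(inclusion_radius = 15))
  expect_equal(length(tab$i), 2)       # 14.9 within radius 15
  s2 <- island_chain(2, 15.1, 15.1)
  tab2 <- build_contact_table(s2$ref, lddt_params(inclusion_radius = 15))
  expect_equal(length(tab2$i), 0)
  # interface variant retains only cross-chain pairs
  fx <- make_complex(c(A = 2), chain_length = 10, seed = 40)
  ref <- cleanup_polymer(fx$ref)
  ti <- build_contact_table(ref, lddt_params(variant = "interface"))
  expect_true(all(ti$atoms$chain[ti$i] != ti$atoms$chain[ti$j]))
  # single-residue structure: empty table, score not computable (never 0)
  one <- qsbench:::new_struct(ref$atoms[ref$atoms$resno == 1 &
                                          ref$atoms$chain == "A", ])
  t1 <- build_contact_table(one)
  expect_equal(length(t1$i), 0)
  r1 <- lddt(one, t1, c(A = "A"), one)
  expect_true(is.na(r1$score))
  expect_match(r1$reason, "contact")
})

test_that("model equals reference gives 1.0 at every threshold", {
  for (seed in 41:43) {
    fx <- make_complex(c(A = 2), chain_length = 12, seed = seed)
    ref <- cleanup_polymer(fx$ref)
    r <- lddt_score(ref, ref, identity_mapping(ref))
    expect_equal(unname(r$fractions), rep(1, 4))
    expect_equal(r$score, 1.0)
  }
})

test_that("optimized engine equals the naive double-loop oracle", {
  cases <- expand.grid(seed = 50:52, radius = c(15, 30),
                       variant = c("full", "backbone", "interface"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    fx <- make_complex(c(A = 2), chain_length = 14, seed = cs$seed,
                       noise = 0.8, perturb_rot = 6)
    cl <- cleaned(fx)
    mp <- identity_mapping(cl$ref)
    tab <- build_contact_table(cl$ref,
                               lddt_params(cs$radius, variant = cs$variant))
    r <- lddt(cl$mdl, tab, mp, cl$ref, symmetry = FALSE)
    o <- oracle_lddt_counts(cl$ref, cl$mdl, mp, cs$radius, cs$variant)
    expect_equal(r$n_contacts, o$total)
    expect_equal(unname(r$preserved), unname(o$preserved))
  }
})

test_that("backbone LDDT on a backbone-only structure equals full LDDT", {
  fx <- make_complex(c(A = 2), chain_length = 12, seed = 53, noise = 0.5)
  cl <- cleaned(fx)
  strip <- function(s) {
    s$atoms <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
    s
  }
  ref_bb <- strip(cl$ref); mdl_bb <- strip(cl$mdl)
  mp <- identity_mapping(cl$ref)
  full_on_bb <- lddt_score(ref_bb, mdl_bb, mp, "full")$score
  bb <- lddt_score(ref_bb, mdl_bb, mp, "backbone")$score
  expect_equal(bb, full_on_bb)
})

test_that("interface LDDT of a monomer is not computable, never 0", {
  fx <- make_complex(c(A = 1), chain_length = 12, seed = 54)
  ref <- cleanup_polymer(fx$ref)
  r <- lddt_score(ref, ref, c(A = "A"), "interface")
  expect_true(is.na(r$score))
})

test_that("LDDT decreases statistically with growing perturbation", {
  scores <- vapply(c(0, 0.3, 1.0, 3.0), function(amp) {
    fx <- make_complex(c(A = 2), chain_length = 14, seed = 55, noise = amp)
    cl <- cleaned(fx)
    lddt_score(cl$ref, cl$mdl, identity_mapping(cl$ref))$score
  }, 0)
  expect_true(all(diff(scores) <= 1e-9))
  expect_equal(scores[1], 1)
})

test_that("OP1/OP2 swaps resolve to chemically equivalent perfection", {
  fx <- make_complex(c(A = 2), chain_length = 8, chain_type = "nucleotide",
                     seed = 56)
  ref <- cleanup_polymer(fx$ref)
  swp <- ref
  for (rn in c(2, 5)) {
    s1 <- swp$atoms$chain == "A" & swp$atoms$resno == rn &
      swp$atoms$atom == "OP1"
    s2 <- swp$atoms$chain == "A" & swp$atoms$resno == rn &
      swp$atoms$atom == "OP2"
    tmp <- swp$atoms[s1, c("x", "y", "z")]
    swp$atoms[s1, c("x", "y", "z")] <- swp$atoms[s2, c("x", "y", "z")]
    swp$atoms[s2, c("x", "y", "z")] <- tmp
  }
  mp <- identity_mapping(ref)
  expect_equal(lddt_score(ref, swp, mp)$score, 1.0, tolerance = 1e-9)
  # without symmetry resolution the swap is penalised
  tab <- build_contact_table(ref, lddt_params())
  expect_lt(lddt(swp, tab, mp, ref, symmetry = FALSE)$score, 1.0)
})

test_that("stereochemistry filter flags violations at the right scope", {
  ip <- make_ideal_peptide(8)
  expect_equal(nrow(stereo_filter(ip)$violations), 0)

  # stretch one CA-CB bond along its own direction by ~0.6 A (~24 sd)
  bad <- ip
  ca <- bad$atoms[bad$atoms$resno == 4 & bad$atoms$atom == "CA",
                  c("x", "y", "z")]
  cb_i <- which(bad$atoms$resno == 4 & bad$atoms$atom == "CB")
  v <- as.numeric(bad$atoms[cb_i, c("x", "y", "z")] - ca)
  bad$atoms[cb_i, c("x", "y", "z")] <-
    ca + (1 + 0.6 / sqrt(sum(v^2))) * v
  res <- stereo_filter(bad)
  expect_equal(nrow(res$violations), 1)
  expect_equal(res$violations$scope, "sidechain")
  expect_false("CB" %in%
                 res$structure$atoms$atom[res$structure$atoms$resno == 4])
  expect_true("CA" %in%
                res$structure$atoms$atom[res$structure$atoms$resno == 4])

  # backbone violation removes the whole residue
  bad2 <- ip
  n_i <- which(bad2$atoms$resno == 4 & bad2$atoms$atom == "N")
  bad2$atoms$x[n_i] <- bad2$atoms$x[n_i] + 2
  res2 <- stereo_filter(bad2)
  expect_true(any(res2$violations$scope == "residue"))
  expect_false(any(res2$structure$atoms$resno == 4))

  # ideal nucleotide passes; a distorted sugar bond is flagged
  inuc <- make_ideal_nucleotide(4)
  expect_equal(nrow(stereo_filter(inuc)$violations), 0)
  badn <- inuc
  seln <- badn$atoms$resno == 2 & badn$atoms$atom == "C5'"
  badn$atoms$z[seln] <- badn$atoms$z[seln] + 0.4
  vn <- stereo_filter(badn)$violations
  expect_gt(nrow(vn), 0)
  expect_true(any(grepl("C5'", vn$atoms)))
})

test_that("clashing atoms are removed by the stereo filter", {
  ip <- make_ideal_peptide(8)
  bad <- ip
  # translate the last residue rigidly on top of residue 1 (internal bonds
  # stay ideal, so the overlap must be caught by the clash check)
  ca1 <- as.numeric(bad$atoms[bad$atoms$resno == 1 &
                                bad$atoms$atom == "CA", c("x", "y", "z")])
  ca8 <- as.numeric(bad$atoms[bad$atoms$resno == 8 &
                                bad$atoms$atom == "CA", c("x", "y", "z")])
  sel <- bad$atoms$resno == 8
  shift <- ca1 + c(0.4, 0, 0) - ca8
  bad$atoms$x[sel] <- bad$atoms$x[sel] + shift[1]
  bad$atoms$y[sel] <- bad$atoms$y[sel] + shift[2]
  bad$atoms$z[sel] <- bad$atoms$z[sel] + shift[3]
  res <- stereo_filter(bad)
  expect_true(any(res$violations$kind == "clash"))
  expect_lt(nrow(res$structure$atoms), nrow(bad$atoms))
})

test_that("stereo violations lower LDDT through unpreserved contacts", {
  ip <- make_ideal_peptide(10)
  bad <- ip
  ca <- bad$atoms[bad$atoms$resno == 5 & bad$atoms$atom == "CA",
                  c("x", "y", "z")]
  cb_i <- which(bad$atoms$resno == 5 & bad$atoms$atom == "CB")
  v <- as.numeric(bad$atoms[cb_i, c("x", "y", "z")] - ca)
  bad$atoms[cb_i, c("x", "y", "z")] <- ca + (1 + 0.5) * v
  tab <- build_contact_table(ip, lddt_params(stereo_checks = TRUE))
  with_checks <- lddt(bad, tab, c(A = "A"), ip)$score
  tab2 <- build_contact_table(ip, lddt_params(stereo_checks = FALSE))
  without <- lddt(bad, tab2, c(A = "A"), ip)$score
  expect_lte(with_checks, without)
})
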