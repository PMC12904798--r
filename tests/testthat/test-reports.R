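test_that("identical complexes score perfectly across the whole report", {
  fx <- make_complex(c(A = 2), chain_length = 14, seed = 100)
  r <- compare_structures(fx$ref, fx$ref)
  expect_equal(r$scores$lddt$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$bb_lddt$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$qs$qs_global$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$qs$qs_best$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$ics_ips$ics$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$ics_ips$ips$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$dockq$dockq_ave$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$gdt$gdt_ts$value, 1.0, tolerance = 1e-9)
  expect_equal(r$scores$rmsd$value, 0.0, tolerance = 1e-9)
})

test_that("per-score failures yield nulls with reasons, not a crash", {
  fx <- make_complex(c(A = 1), chain_length = 12, seed = 101)
  r <- compare_structures(fx$ref, fx$model,
                          scores = c("lddt", "ilddt", "qs_score", "dockq"))
  expect_equal(r$scores$lddt$value, 1.0)
  expect_null(r$scores$ilddt$value)      # monomer: no interface
  expect_null(r$scores$qs$qs_global$value)
  expect_null(r$scores$dockq$dockq_ave$value)
  expect_false(is.null(r$scores$ilddt$reason))
})

test_that("wrong model stoichiometry separates qs_global from qs_best", {
  dimer <- make_complex(c(A = 2), chain_length = 12, seed = 102)
  tetra <- make_complex(c(A = 4), chain_length = 12, seed = 102)
  r <- compare_structures(dimer$ref, tetra$ref, scores = "qs_score")
  expect_lt(r$scores$qs$qs_global$value, r$scores$qs$qs_best$value)
})

test_that("the capri-peptide flag toggles DockQ parameters only", {
  fx <- make_complex(c(A = 2), chain_length = 14, seed = 103, noise = 0.5)
  r1 <- compare_structures(fx$ref, fx$model,
                           scores = c("dockq", "ics_ips"))
  r2 <- compare_structures(fx$ref, fx$model,
                           scores = c("dockq", "ics_ips"),
                           dockq_capri_peptide = TRUE)
  expect_equal(r1$scores$ics_ips$ics$value, r2$scores$ics_ips$ics$value)
  expect_false(isTRUE(all.equal(r1$scores$dockq$per_interface[[1]]$irmsd,
                                r2$scores$dockq$per_interface[[1]]$irmsd)))
})

test_that("residue-number alignment is honoured end to end", {
  fx <- make_complex(c(A = 2), chain_length = 14, seed = 104, noise = 0.3)
  r <- compare_structures(fx$ref, fx$model, scores = c("lddt", "rmsd"),
                          residue_number_alignment = TRUE)
  expect_equal(r$meta$alignment_mode, "residue_number")
  expect_gt(r$scores$lddt$value, 0.5)
})

test_that("reports are byte-stable across repeated runs", {
  fx <- make_complex(c(A = 2, B = 1), chain_length = c(12, 10), seed = 105,
                     noise = 0.4)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(compare_structures(fx$ref, fx$model), f1)
  write_report_json(compare_structures(fx$ref, fx$model), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ligand comparison reports per-pair scores and two assignments", {
  fx <- make_complex(c(A = 2), chain_length = 16, seed = 106,
                     ligand = "ring", ligand_shift = 0.6)
  r <- compare_ligand_structures(fx$ref, fx$model)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$bisy_rmsd, 0.6, tolerance = 1e-9)
  expect_equal(nrow(r$assignment_bisy_rmsd$pairs), 1)
  expect_equal(nrow(r$assignment_lddt_pli$pairs), 1)
  # redock in identical frames: symmetry-corrected RMSD with superposition
  # equals the plain shift
  expect_equal(r$pairs$rmsd_lp, 0, tolerance = 1e-9)
})

test_that("two-ligand fixtures produce independent one-to-one assignments", {
  fx <- make_complex(c(A = 2), chain_length = 16, seed = 107,
                     ligand = "ring")
  ref <- fx$ref
  # second copy of the ligand on the other chain
  lg2 <- ref$ligands[[1]]
  a2 <- ref$atoms[ref$atoms$chain == "B" & ref$atoms$atom == "CA", ]
  anchor <- as.numeric(a2[ceiling(nrow(a2) / 2), c("x", "y", "z")])
  sh <- anchor + c(0, 0, 4) - colMeans(as.matrix(lg2$atoms[, c("x", "y", "z")]))
  lg2$atoms$x <- lg2$atoms$x + sh[1]
  lg2$atoms$y <- lg2$atoms$y + sh[2]
  lg2$atoms$z <- lg2$atoms$z + sh[3]
  ref$ligands <- c(ref$ligands, list(lg2))
  mdl <- ref
  mdl$ligands[[2]]$atoms$x <- mdl$ligands[[2]]$atoms$x + 1.0
  r <- compare_ligand_structures(ref, mdl)
  expect_equal(nrow(r$pairs), 4)     # 2 x 2 isomorphic pairs
  expect_equal(nrow(r$assignment_bisy_rmsd$pairs), 2)
  expect_equal(nrow(r$assignment_lddt_pli$pairs), 2)
  # assignments are one-to-one
  expect_equal(anyDuplicated(r$assignment_bisy_rmsd$pairs$mdl), 0)
  expect_equal(anyDuplicated(r$assignment_lddt_pli$pairs$ref), 0)
})

test_that("substructure matches report partial coverage", {
  fx <- make_complex(c(A = 2), chain_length = 16, seed = 108,
                     ligand = "linear")
  ref <- fx$ref
  # reference ligand misses two atoms (unresolved density)
  ref$ligands[[1]]$atoms <- ref$ligands[[1]]$atoms[1:2, ]
  ref$ligands[[1]]$bonds <- ref$ligands[[1]]$bonds[1, , drop = FALSE]
  r <- compare_ligand_structures(ref, fx$model, substructure_match = TRUE)
  expect_equal(r$pairs$coverage, 0.5)
})

test_that("the command-line actions run over files and write reports", {
  cli_dir <- system.file("cli", package = "qsbench")
  fx <- make_complex(c(A = 2), chain_length = 12, seed = 109, noise = 0.3)
  ref <- withr::local_tempfile(fileext = ".cif")
  mdl <- withr::local_tempfile(fileext = ".pdb")
  out <- withr::local_tempfile(fileext = ".json")
  write_structure_mmcif(fx$ref, ref)
  write_structure_pdb(fx$model, mdl)
  res <- system2("Rscript",
                 c(file.path(cli_dir, "compare-structures.R"),
                   "--reference", ref, "--model", mdl,
                   "--lddt", "--qs-score", "--rmsd", "--output", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  js <- jsonlite::read_json(out)
  expect_gt(js$scores$lddt$value, 0.3)

  # ligand action with SDF inputs
  fxl <- make_complex(c(A = 2), chain_length = 14, seed = 110,
                      ligand = "ring", ligand_shift = 0.5)
  refl <- withr::local_tempfile(fileext = ".pdb")
  mdll <- withr::local_tempfile(fileext = ".pdb")
  sref <- withr::local_tempfile(fileext = ".sdf")
  smdl <- withr::local_tempfile(fileext = ".sdf")
  outl <- withr::local_tempfile(fileext = ".json")
  write_structure_pdb(fxl$ref, refl)
  write_structure_pdb(fxl$model, mdll)
  write_ligand_sdf(fxl$ref$ligands[[1]], sref)
  write_ligand_sdf(fxl$model$ligands[[1]], smdl)
  system2("Rscript",
          c(file.path(cli_dir, "compare-ligand-structures.R"),
            "--reference", refl, "--model", mdll,
            "--reference-ligands", sref, "--model-ligands", smdl,
            "--output", outl),
          stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(outl))
  jl <- jsonlite::read_json(outl)
  expect_equal(jl$pairs[[1]]$bisy_rmsd, 0.5, tolerance = 1e-6)
})
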