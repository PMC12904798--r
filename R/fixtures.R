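# Deterministic synthetic-structure generator. Coordinates are parametric
# (helix-like curves, cyclic ring placement of chains) rather than drawn
# from real structures: every test surface gets a complex with known ground
# truth. Stereochemically ideal fixtures for the stereo filter are built
# separately by make_ideal_peptide()/make_ideal_nucleotide().

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

random_sequence <- function(n, type = "peptide") {
  if (type == "nucleotide") paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                  collapse = "")
  else paste(sample(names(aa_three), n, TRUE), collapse = "")
}

# decorative helix chain: plausible local geometry, exact only where tests
# require it (see make_ideal_peptide)
helix_chain_atoms <- function(seq1, chain_id, type = "peptide") {
  n <- nchar(seq1)
  letters1 <- strsplit(seq1, "")[[1]]
  if (type == "peptide") {
    r <- 2.3; rise <- 1.5; step <- 100 * pi / 180
    offs <- list(N = c(-1.20, 0.60, 0.30), CA = c(0, 0, 0),
                 C = c(1.25, 0.50, -0.20), O = c(1.80, 1.55, -0.40),
                 CB = c(0.10, -1.45, 0.55))
    resid3 <- aa_three[letters1]
  } else {
    r <- 9; rise <- 2.8; step <- 36 * pi / 180
    offs <- list(P = c(3.2, 1.2, 3.2), OP1 = c(4.4, 0.6, 3.6),
                 OP2 = c(3.3, 2.7, 3.1), `O5'` = c(2.5, 0.6, 2.1),
                 `C5'` = c(2.0, 1.2, 1.0), `C4'` = c(1.0, 0.8, 0.3),
                 `O4'` = c(2.2, -0.1, 0.0), `C3'` = c(0, 0, 0),
                 `O3'` = c(-1.1, 0.5, -0.8), `C2'` = c(0.3, -1.4, -0.5),
                 `O2'` = c(-0.3, -2.5, 0.1), `C1'` = c(1.8, -1.4, -0.3))
    resid3 <- letters1
  }
  rows <- list()
  for (i in seq_len(n)) {
    th <- step * i
    ca <- c(r * cos(th), r * sin(th), rise * i)
    e2 <- c(cos(th), sin(th), 0)                       # radial, outward
    e1 <- c(-sin(th), cos(th), rise / (r * step))
    e1 <- e1 / sqrt(sum(e1^2))
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    frame <- cbind(e1, e2, e3)
    res <- resid3[i]
    at_names <- names(offs)
    if (type == "peptide" && res == "GLY")
      at_names <- setdiff(at_names, "CB")
    if (type == "nucleotide") {
      base <- switch(res,
                     A = list(N9 = c(2.7, -2.4, -0.9), C8 = c(2.6, -3.7, -0.6)),
                     G = list(N9 = c(2.7, -2.4, -0.9), C8 = c(2.6, -3.7, -0.6)),
                     C = list(N1 = c(2.7, -2.4, -0.9), C2 = c(2.6, -3.7, -0.6)),
                     U = list(N1 = c(2.7, -2.4, -0.9), C2 = c(2.6, -3.7, -0.6)))
      offs_i <- c(offs, base)
      at_names <- names(offs_i)
    } else offs_i <- offs
    for (at in at_names) {
      p <- ca + as.numeric(frame %*% offs_i[[at]])
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain_id, resno = i, ins = "", resid = res, atom = at,
        elem = derive_element(at), x = p[1], y = p[2], z = p[3],
        occ = 1, het = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

transform_atoms <- function(atoms, R = diag(3), t = c(0, 0, 0),
                            center = NULL) {
  xyz <- coords(atoms)
  if (is.null(center)) center <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center + t, `+`)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

random_rotation <- function(max_angle_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about(ax, stats::runif(1, -1, 1) * max_angle_deg * pi / 180)
}

#' Generate a synthetic complex with known ground truth
#'
#' Builds a reference complex of helix-like chains placed on a ring
#' (identical sequences within each stoichiometry group) and a model derived
#' from it by optional per-chain rigid perturbations, per-atom Gaussian
#' noise, chain relabeling, a domain-hinge rotation and a global rigid
#' transform. Identical seed and arguments give identical structures.
#'
#' @param stoichiometry named integer vector, e.g. `c(A = 3)` (homotrimer)
#'   or `c(A = 2, B = 2)`; names label sequence groups.
#' @param chain_length residues per chain (recycled over groups).
#' @param chain_type `"peptide"` or `"nucleotide"` (recycled over groups).
#' @param seed integer seed.
#' @param noise per-coordinate Gaussian sd (A) applied to the model.
#' @param perturb_rot,perturb_trans per-chain rigid perturbation of the
#'   model: rotation (degrees, uniform in +-value) and translation sd (A).
#' @param relabel `NULL`, `"cycle"`, `"random"`, or a named character
#'   vector mapping reference to model chain ids (within groups).
#' @param hinge optional `list(chain=, from=, angle=)`: rotate residues
#'   `>= from` of one model chain by `angle` degrees.
#' @param global_rot global rigid rotation of the model (degrees; 0 = off).
#' @param ligand optional template name passed to [make_ligand()]; the
#'   ligand is placed against the middle of the first chain and attached to
#'   both structures.
#' @param ligand_shift translation (A, vector or scalar x-shift) applied to
#'   the model copy of the ligand.
#' @param ring_gap target distance between adjacent chain axes (A).
#' @return list `ref`, `model` (`struct`s), `truth` (mapping etc.).
#' @export
make_complex <- function(stoichiometry = c(A = 2), chain_length = 24,
                         chain_type = "peptide", seed = 1, noise = 0,
                         perturb_rot = 0, perturb_trans = 0,
                         relabel = NULL, hinge = NULL, global_rot = 0,
                         ligand = NULL, ligand_shift = 0,
                         ring_gap = 10.5) {
  with_seed(seed, {
    groups <- names(stoichiometry)
    chain_length <- rep(chain_length, length.out = length(groups))
    chain_type <- rep(chain_type, length.out = length(groups))
    seqs <- lapply(seq_along(groups), function(g)
      random_sequence(chain_length[g], chain_type[g]))
    n_chains <- sum(stoichiometry)
    ids <- LETTERS[seq_len(n_chains)]
    ring_r <- if (n_chains > 1) ring_gap / (2 * sin(pi / n_chains)) else 0
    atoms <- list()
    ent <- list()
    chain_group <- character(0)
    k <- 0
    for (g in seq_along(groups)) {
      for (copy in seq_len(stoichiometry[g])) {
        k <- k + 1
        ch <- helix_chain_atoms(seqs[[g]], ids[k], chain_type[g])
        ang <- 2 * pi * (k - 1) / n_chains
        ch <- transform_atoms(ch, rotation_about(c(0, 0, 1), ang),
                              t = c(ring_r * cos(ang), ring_r * sin(ang), 0),
                              center = c(0, 0, 0))
        atoms[[k]] <- ch
        chain_group[ids[k]] <- groups[g]
        ent[[k]] <- data.frame(chain = ids[k], entity_id = as.character(g),
                               entity_type = "polymer", seq = seqs[[g]],
                               stringsAsFactors = FALSE)
      }
    }
    ref <- new_struct(do.call(rbind, atoms), entities = do.call(rbind, ent))

    # ligand placed against the middle of chain 1, pointing outward
    if (!is.null(ligand)) {
      lg <- make_ligand(ligand)
      a1 <- ref$atoms[ref$atoms$chain == ids[1], , drop = FALSE]
      mid <- a1[a1$atom %in% c("CA", "C3'"), , drop = FALSE]
      anchor <- as.numeric(mid[ceiling(nrow(mid) / 2), c("x", "y", "z")])
      dir <- anchor - c(0, 0, anchor[3])
      dir <- if (sqrt(sum(dir^2)) > 0) dir / sqrt(sum(dir^2)) else c(1, 0, 0)
      shift <- anchor + 3.4 * dir - colMeans(coords(lg$atoms))
      lg$atoms$x <- lg$atoms$x + shift[1]
      lg$atoms$y <- lg$atoms$y + shift[2]
      lg$atoms$z <- lg$atoms$z + shift[3]
      ref$ligands <- list(lg)
    }

    mdl <- ref
    truth_map <- stats::setNames(ids, ids)
    for (ch in ids) {
      sel <- mdl$atoms$chain == ch
      sub <- mdl$atoms[sel, , drop = FALSE]
      if (perturb_rot > 0 || perturb_trans > 0)
        sub <- transform_atoms(sub, random_rotation(perturb_rot),
                               t = stats::rnorm(3, 0, perturb_trans))
      mdl$atoms[sel, ] <- sub
    }
    if (!is.null(hinge)) {
      sel <- mdl$atoms$chain == hinge$chain & mdl$atoms$resno >= hinge$from
      piv <- mdl$atoms[mdl$atoms$chain == hinge$chain &
                         mdl$atoms$resno == hinge$from &
                         mdl$atoms$atom %in% c("CA", "C3'"), , drop = FALSE]
      pivot <- as.numeric(piv[1, c("x", "y", "z")])
      Rh <- rotation_about(c(1, 0, 0), hinge$angle * pi / 180)
      sub <- mdl$atoms[sel, , drop = FALSE]
      xyz <- sweep(sweep(coords(sub), 2, pivot) %*% t(Rh), 2, pivot, `+`)
      sub$x <- xyz[, 1]; sub$y <- xyz[, 2]; sub$z <- xyz[, 3]
      mdl$atoms[sel, ] <- sub
    }
    if (noise > 0) {
      mdl$atoms$x <- mdl$atoms$x + stats::rnorm(nrow(mdl$atoms), 0, noise)
      mdl$atoms$y <- mdl$atoms$y + stats::rnorm(nrow(mdl$atoms), 0, noise)
      mdl$atoms$z <- mdl$atoms$z + stats::rnorm(nrow(mdl$atoms), 0, noise)
    }
    if (length(mdl$ligands)) {
      sh <- if (length(ligand_shift) == 1) c(ligand_shift, 0, 0)
            else ligand_shift
      mdl$ligands[[1]]$atoms$x <- mdl$ligands[[1]]$atoms$x + sh[1]
      mdl$ligands[[1]]$atoms$y <- mdl$ligands[[1]]$atoms$y + sh[2]
      mdl$ligands[[1]]$atoms$z <- mdl$ligands[[1]]$atoms$z + sh[3]
    }
    if (global_rot != 0) {
      Rg <- random_rotation(global_rot)
      tg <- stats::rnorm(3, 0, 5)
      mdl$atoms <- transform_atoms(mdl$atoms, Rg, tg)
      for (i in seq_along(mdl$ligands))
        mdl$ligands[[i]]$atoms <- transform_atoms(mdl$ligands[[i]]$atoms,
                                                  Rg, tg)
    }
    if (!is.null(relabel)) {
      perm <- relabel
      if (identical(relabel, "cycle") || identical(relabel, "random")) {
        perm <- character(0)
        for (g in groups) {
          member <- ids[chain_group[ids] == g]
          new <- if (identical(relabel, "cycle"))
            member[c(seq_along(member)[-1], 1)]
          else sample(member)
          perm[member] <- new
        }
      }
      mdl$atoms$chain <- unname(perm[mdl$atoms$chain])
      mdl$atoms <- mdl$atoms[order(match(mdl$atoms$chain, ids)), ,
                             drop = FALSE]
      if (!is.null(mdl$entities))
        mdl$entities$chain <- unname(perm[mdl$entities$chain])
      truth_map <- perm
    }
    list(ref = ref, model = mdl,
         truth = list(mapping = truth_map, groups = chain_group,
                      sequences = stats::setNames(unlist(seqs), groups)))
  })
}

#' Generate a template ligand
#'
#' Templates: `ring` (benzene-like C6 ring, 12 automorphisms), `linear`
#' (n-butane chain), `ion` (single Mg), `fragments` (two disconnected
#' 2-carbon pieces, reproducing disconnected-ligand scenarios).
#'
#' @param template template name.
#' @param pose optional `list(R =, t =)` rigid transform.
#' @return a `lig` object (convert with [write_ligand_sdf()] if needed).
#' @export
make_ligand <- function(template = c("ring", "linear", "ion", "fragments"),
                        pose = NULL) {
  template <- match.arg(template)
  mk <- function(el, xyz, bonds, name) {
    new_ligand(name = name,
               atoms = data.frame(atom = paste0(el, seq_along(el)),
                                  elem = el, x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3], stringsAsFactors = FALSE),
               bonds = bonds, source = "generated")
  }
  # names double as component codes (BNZ/MG are in the bundled dictionary)
  lig <- switch(template,
    ring = {
      th <- 2 * pi * (0:5) / 6
      mk(rep("C", 6), cbind(1.39 * cos(th), 1.39 * sin(th), 0),
         data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1L), "BNZ")
    },
    linear = mk(rep("C", 4),
                cbind(1.27 * (0:3), 0.77 * (0:3 %% 2), 0),
                data.frame(a1 = 1:3, a2 = 2:4, order = 1L), "LIG"),
    ion = mk("MG", matrix(0, 1, 3), NULL, "MG"),
    fragments = mk(rep("C", 4),
                   rbind(c(0, 0, 0), c(1.5, 0, 0),
                         c(6, 0, 0), c(7.5, 0, 0)),
                   data.frame(a1 = c(1, 3), a2 = c(2, 4), order = 1L),
                   "FRG"))
  if (!is.null(pose))
    lig$atoms <- transform_atoms(lig$atoms, pose$R %||% diag(3),
                                 pose$t %||% c(0, 0, 0), center = c(0, 0, 0))
  lig
}

# internal-coordinate atom placement (NeRF): position at given bond length,
# angle (deg, at b) and dihedral (deg, a-b-c-new)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180; dih <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
         bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Stereochemically ideal extended peptide chain
#'
#' Backbone built at exact ideal bond lengths and angles (trans
#' conformation), CB at the ideal CA-CB length: passes [stereo_filter()]
#' with zero violations.
#'
#' @param n residues; @param chain_id chain id; @param sequence optional
#'   one-letter sequence (default poly-alanine with one glycine).
#' @return a `struct`.
#' @export
make_ideal_peptide <- function(n = 8, chain_id = "A", sequence = NULL) {
  seq1 <- sequence %||% paste(rep("A", n), collapse = "")
  letters1 <- strsplit(seq1, "")[[1]]
  n <- length(letters1)
  rows <- list()
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, 1.525, 111.0, 150)
  for (i in seq_len(n)) {
    res <- aa_three[letters1[i]]
    O <- place_atom(N, CA, C, 1.231, 120.1, 0)
    add <- function(at, p) rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain_id, resno = i, ins = "", resid = res, atom = at,
      elem = derive_element(at), x = p[1], y = p[2], z = p[3], occ = 1,
      het = FALSE, stringsAsFactors = FALSE)
    add("N", N); add("CA", CA); add("C", C); add("O", O)
    if (res != "GLY") add("CB", place_atom(C, N, CA, 1.530, 110.5, 122.5))
    if (i < n) {
      N2 <- place_atom(N, CA, C, 1.329, 116.2, 180)
      CA2 <- place_atom(CA, C, N2, 1.458, 121.7, 180)
      C2 <- place_atom(C, N2, CA2, 1.525, 111.0, 180)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  new_struct(do.call(rbind, rows))
}

#' Approximately ideal single nucleotide chain for stereo tests
#'
#' Atoms placed sequentially so that every bond and angle checked by the
#' bundled restraint table is satisfied exactly; ring closure bonds are
#' solved by sphere intersection.
#'
#' @param n residues; @param chain_id chain id.
#' @return a `struct` of poly-U.
#' @export
make_ideal_nucleotide <- function(n = 4, chain_id = "A") {
  rows <- list()
  P <- c(0, 0, 0)
  prev_O3 <- NULL
  dirseed <- c(1, 0.3, 0.15)
  for (i in seq_len(n)) {
    add <- function(at, p) rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain_id, resno = i, ins = "", resid = "U", atom = at,
      elem = derive_element(at), x = p[1], y = p[2], z = p[3], occ = 1,
      het = FALSE, stringsAsFactors = FALSE)
    if (!is.null(prev_O3)) P <- prev_O3 + 1.607 * c(1, 0, 0)
    OP1 <- P + 1.485 * c(0, 1, 0)
    OP2 <- P + 1.485 * c(0, -0.7, 0.714) / sqrt(sum(c(0, -0.7, 0.714)^2))
    O5 <- P + 1.593 * dirseed / sqrt(sum(dirseed^2))
    C5 <- place_atom(OP1, P, O5, 1.440, 120, 60)
    C4 <- place_atom(P, O5, C5, 1.510, 111.5, 170)
    C3 <- place_atom(O5, C5, C4, 1.524, 115.5, 170)
    O3 <- place_atom(C5, C4, C3, 1.423, 110.3, 160)
    O4 <- place_atom(O5, C5, C4, 1.453, 109, -60)
    # close the furanose ring by sphere intersection: C1' at the O4' bond
    # length and within reach of C3'; C2' bonded to both C1' and C3'
    C1 <- sphere_mid(O4, 1.414, C3, 2.35, up = C5)
    C2 <- sphere_mid(C1, 1.528, C3, 1.525, up = 2 * C4 - O4)
    O2 <- C2 + 1.413 * normalize(C2 - (C1 + C3) / 2)
    N1 <- C1 + 1.48 * normalize(C1 - O4)
    C2b <- N1 + 1.38 * normalize(N1 - C1)
    add("P", P); add("OP1", OP1); add("OP2", OP2); add("O5'", O5)
    add("C5'", C5); add("C4'", C4); add("O4'", O4); add("C3'", C3)
    add("O3'", O3); add("C2'", C2); add("O2'", O2); add("C1'", C1)
    add("N1", N1); add("C2", C2b)
    prev_O3 <- O3
  }
  new_struct(do.call(rbind, rows))
}

normalize <- function(v) v / sqrt(sum(v^2))

# a point at distance r1 from p1 and r2 from p2, displaced towards `up`
sphere_mid <- function(p1, r1, p2, r2, up) {
  d <- sqrt(sum((p2 - p1)^2))
  stopifnot(d < r1 + r2)
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h <- sqrt(max(r1^2 - a^2, 0))
  base <- p1 + a * normalize(p2 - p1)
  perp <- up - base
  perp <- perp - sum(perp * normalize(p2 - p1)) * normalize(p2 - p1)
  base + h * normalize(perp)
}
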