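#' Stereochemistry restraint library
#'
#' Loads the bundled table of ideal bond lengths and angles with standard
#' deviations for peptide and nucleotide backbones (a curated table of
#' standard restraint values). `+X` in an atom field refers to atom `X` of
#' the next residue in the chain.
#'
#' @param path optional TSV with columns kind, restype, a1, a2, a3, ideal, sd.
#' @return data frame of class `stereo_library`.
#' @export
stereo_library <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.qsbench_cache$stereo)) return(.qsbench_cache$stereo)
    path <- system.file("extdata", "stereo_lib.tsv", package = "qsbench")
  }
  lib <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  class(lib) <- c("stereo_library", class(lib))
  .qsbench_cache$stereo <- lib
  lib
}

angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

peptide_backbone <- c("N", "CA", "C", "O")
nucleotide_backbone <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                         "C3'", "O3'", "C2'", "O2'", "C1'")

#' Stereochemistry filter applied to models before LDDT
#'
#' Flags bonds and angles deviating from ideal values by more than
#' `tolerance` standard deviations, and steric clashes (non-bonded atoms from
#' different residues closer than the sum of covalent radii minus 0.4 A).
#' Side-chain violations remove the offending side chain; backbone violations
#' remove the whole residue; clashing atoms are removed. Removed atoms make
#' their reference contacts score as unpreserved.
#'
#' @param mdl model `struct`.
#' @param lib [stereo_library()].
#' @param tolerance allowed deviation in standard deviations.
#' @param dict chemical component dictionary.
#' @return list: filtered `structure`, `violations` data frame.
#' @export
stereo_filter <- function(mdl, lib = stereo_library(), tolerance = 12,
                          dict = ccd_dictionary()) {
  a <- mdl$atoms
  ty <- chain_types(mdl, dict)
  viol <- list()
  drop_atom <- rep(FALSE, nrow(a))
  akey <- paste(res_key(a), a$atom)
  find_atom <- function(key) match(key, akey)

  for (ch in struct_chains(mdl)) {
    if (!ty[ch] %in% c("peptide", "nucleotide")) next
    res <- chain_residues(mdl, ch)
    sub <- lib[lib$restype == ty[ch], , drop = FALSE]
    bb <- if (ty[ch] == "peptide") peptide_backbone else nucleotide_backbone
    for (ri in seq_len(nrow(res))) {
      key <- res$key[ri]
      nxt <- if (ri < nrow(res)) res$key[ri + 1] else NA
      resolve <- function(at) {
        if (startsWith(at, "+")) {
          if (is.na(nxt)) return(NA_integer_)
          find_atom(paste(nxt, substring(at, 2)))
        } else find_atom(paste(key, at))
      }
      for (k in seq_len(nrow(sub))) {
        rw <- sub[k, ]
        i1 <- resolve(rw$a1); i2 <- resolve(rw$a2)
        if (is.na(i1) || is.na(i2)) next
        if (rw$kind == "bond") {
          val <- sqrt(sum((coords(a)[i1, ] - coords(a)[i2, ])^2))
        } else {
          i3 <- resolve(rw$a3)
          if (is.na(i3)) next
          val <- angle_deg(coords(a)[i1, ], coords(a)[i2, ], coords(a)[i3, ])
        }
        if (abs(val - rw$ideal) > tolerance * rw$sd) {
          atoms_involved <- c(rw$a1, rw$a2, if (rw$kind == "angle") rw$a3)
          atoms_involved <- sub("^\\+", "", atoms_involved)
          backbone_hit <- all(atoms_involved %in% bb)
          viol[[length(viol) + 1L]] <- data.frame(
            chain = ch, key = key, kind = rw$kind,
            atoms = paste(atoms_involved, collapse = "-"),
            value = val, ideal = rw$ideal, sd = rw$sd,
            scope = if (backbone_hit) "residue" else "sidechain",
            stringsAsFactors = FALSE)
          sel <- which(res_key(a) == key)
          if (backbone_hit) drop_atom[sel] <- TRUE
          else drop_atom[sel[!(a$atom[sel] %in% bb)]] <- TRUE
        }
      }
    }
  }

  # clash check between atoms of different residues, excluding the
  # backbone link partners
  heavy <- which(a$elem != "H" & !drop_atom)
  if (length(heavy) > 1) {
    d <- cross_dist(coords(a)[heavy, , drop = FALSE],
                    coords(a)[heavy, , drop = FALSE])
    rk <- res_key(a)[heavy]
    rad <- covalent_radius(a$elem[heavy])
    lim <- outer(rad, rad, `+`) - 0.4
    clash <- d < lim & upper.tri(d) & outer(rk, rk, `!=`)
    linked <- (a$atom[heavy[row(d)]] %in% c("C", "O3'") &
                 a$atom[heavy[col(d)]] %in% c("N", "P")) |
      (a$atom[heavy[col(d)]] %in% c("C", "O3'") &
         a$atom[heavy[row(d)]] %in% c("N", "P"))
    clash <- clash & !matrix(linked, nrow(d))
    hit <- which(clash, arr.ind = TRUE)
    if (nrow(hit)) {
      ids <- unique(c(heavy[hit[, 1]], heavy[hit[, 2]]))
      drop_atom[ids] <- TRUE
      viol[[length(viol) + 1L]] <- data.frame(
        chain = a$chain[ids], key = res_key(a)[ids], kind = "clash",
        atoms = a$atom[ids], value = NA_real_, ideal = NA_real_,
        sd = NA_real_, scope = "atom", stringsAsFactors = FALSE)
    }
  }

  out <- new_struct(a[!drop_atom, , drop = FALSE], entities = mdl$entities,
                    ligands = mdl$ligands, source_format = mdl$source_format)
  list(structure = out,
       violations = if (length(viol)) do.call(rbind, viol)
                    else data.frame())
}
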