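# Ligand representation: heavy atoms plus explicit connectivity.
#   atoms - data.frame(atom, elem, x, y, z[, charge])
#   bonds - data.frame(a1, a2, order) with 1-based atom indices
#   source - "sdf" | "ccd" | "heuristic" | "generated"

new_ligand <- function(name, atoms, bonds, source = "generated",
                       n_hydrogens_removed = 0L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  rownames(atoms) <- NULL
  if (is.null(bonds) || nrow(bonds) == 0)
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(atoms) - igraph::vcount(g)))
  multi_fragment <- igraph::components(g)$no > 1
  structure(list(name = name, atoms = atoms, bonds = bonds, source = source,
                 multi_fragment = multi_fragment,
                 n_hydrogens_removed = n_hydrogens_removed),
            class = "lig")
}

#' @export
print.lig <- function(x, ...) {
  cat(sprintf("<ligand> %s: %d heavy atoms, %d bonds (source: %s%s)\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$source,
              if (x$multi_fragment) ", multi-fragment" else ""))
  invisible(x)
}

#' Read a ligand from an SDF (V2000) file
#'
#' Connectivity is taken verbatim from the bond block; hydrogens are removed
#' (their count is recorded). Charge fields (`M  CHG`) are preserved on the
#' atom table but not used for matching.
#'
#' @param path SDF file; the first molecule block is read.
#' @return a `lig` object.
#' @export
read_ligand_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("not a valid SDF file: ", path, call. = FALSE)
  counts <- lines[4]
  n_at <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_at) || is.na(n_bd))
    stop("malformed SDF counts line in ", path, call. = FALSE)
  end <- which(grepl("^M  END", lines))[1]
  body <- if (is.na(end)) lines[-(1:4)] else lines[5:(end - 1)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n_at + n_bd)
    stop("SDF atom/bond block shorter than counts line in ", path,
         call. = FALSE)
  atom_lines <- body[seq_len(n_at)]
  looks_atom <- grepl("^\\s*-?\\d+\\.\\d+\\s+-?\\d+\\.\\d+\\s+-?\\d+\\.\\d+\\s+[A-Za-z]",
                      atom_lines)
  if (!all(looks_atom))
    stop("SDF atom count does not match atom block in ", path, call. = FALSE)
  if (n_bd == 0 && n_at > 1)
    stop("SDF file ", path, " has no bond block; explicit connectivity ",
         "is required", call. = FALSE)
  parse_atom <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    list(x = as.numeric(f[1]), y = as.numeric(f[2]), z = as.numeric(f[3]),
         elem = toupper(f[4]))
  }
  at <- lapply(atom_lines, parse_atom)
  atoms <- data.frame(atom = paste0(vapply(at, `[[`, "", "elem"),
                                    seq_len(n_at)),
                      elem = vapply(at, `[[`, "", "elem"),
                      x = vapply(at, `[[`, 0, "x"),
                      y = vapply(at, `[[`, 0, "y"),
                      z = vapply(at, `[[`, 0, "z"),
                      charge = 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  if (n_bd > 0) {
    bl <- body[n_at + seq_len(n_bd)]
    bonds <- data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
    if (anyNA(bonds))
      stop("SDF bond count does not match bond block in ", path, call. = FALSE)
  }
  if (!is.na(end)) {
    for (chg in grep("^M  CHG", lines, value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg)), "\\s+")[[1]])
      np <- f[1]
      for (j in seq_len(np))
        atoms$charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  # drop hydrogens, reindex bonds
  is_h <- atoms$elem == "H"
  nh <- sum(is_h)
  if (nh > 0) {
    map <- cumsum(!is_h)
    bonds <- bonds[!is_h[bonds$a1] & !is_h[bonds$a2], , drop = FALSE]
    bonds$a1 <- map[bonds$a1]
    bonds$a2 <- map[bonds$a2]
    atoms <- atoms[!is_h, , drop = FALSE]
  }
  nm <- trimws(lines[1])
  new_ligand(name = if (nzchar(nm)) nm else basename(path),
             atoms = atoms, bonds = bonds, source = "sdf",
             n_hydrogens_removed = nh)
}

#' Write a ligand as SDF V2000 text
#' @param lig a `lig`; @param path optional output file.
#' @return the SDF text, invisibly when `path` is given.
#' @export
write_ligand_sdf <- function(lig, path = NULL) {
  a <- lig$atoms
  b <- lig$bonds
  txt <- c(lig$name, "  qsbench", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   a$x, a$y, a$z, substr(paste0(toupper(substr(a$elem, 1, 1)),
                                                tolower(substr(a$elem, 2, 2))), 1, 2)))
  if (nrow(b))
    txt <- c(txt, sprintf("%3d%3d%3d  0", b$a1, b$a2,
                          ifelse(is.na(b$order) | b$order < 1, 1, b$order)))
  txt <- c(txt, "M  END", "$$$$")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

# Bond derivation for ligands taken from coordinate files:
# CCD lookup first, then a van-der-Waals distance heuristic.
ligand_bonds_for <- function(lig_atoms, code, dict,
                             vdw_factor = 0.6) {
  cb <- ccd_bonds(dict, code)
  if (!is.null(cb)) {
    a1 <- match(cb$atom1, lig_atoms$atom)
    a2 <- match(cb$atom2, lig_atoms$atom)
    ok <- !is.na(a1) & !is.na(a2)
    return(list(bonds = data.frame(a1 = a1[ok], a2 = a2[ok],
                                   order = rep(1L, sum(ok))),
                source = "ccd"))
  }
  xyz <- coords(lig_atoms)
  n <- nrow(xyz)
  if (n < 2) return(list(bonds = NULL, source = "heuristic"))
  d <- cross_dist(xyz, xyz)
  r <- vdw_radius(lig_atoms$elem)
  thr <- vdw_factor * outer(r, r, `+`)
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  list(bonds = data.frame(a1 = hit[, 1], a2 = hit[, 2], order = 1L),
       source = "heuristic")
}
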