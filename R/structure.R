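#' @importFrom stats setNames
NULL

# Internal representation: a structure is a list with
#   atoms    - data.frame(chain, resno, ins, resid, atom, elem, x, y, z, occ, het)
#   entities - optional data.frame(chain, entity_id, entity_type, seq)
#   ligands  - list of `lig` objects (see ligand.R)
#   source_format - "mmcif" | "pdb" | "generated"
# Residues are identified by (chain, resno, ins); ordering is file order.

new_struct <- function(atoms, entities = NULL, ligands = list(),
                       source_format = "generated") {
  atoms$ins[is.na(atoms$ins)] <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, entities = entities, ligands = ligands,
                 source_format = source_format),
            class = "struct")
}

#' @export
print.struct <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<struct> %d chain(s) [%s], %d atoms, %d ligand(s), source: %s\n",
              length(ch), paste(ch, collapse = ","), nrow(x$atoms),
              length(x$ligands), x$source_format))
  invisible(x)
}

atom_cols <- c("chain", "resno", "ins", "resid", "atom", "elem",
               "x", "y", "z", "occ", "het")

empty_atoms <- function() {
  data.frame(chain = character(), resno = integer(), ins = character(),
             resid = character(), atom = character(), elem = character(),
             x = double(), y = double(), z = double(), occ = double(),
             het = logical(), stringsAsFactors = FALSE)
}

res_key <- function(a) paste(a$chain, a$resno, a$ins, sep = "|")

coords <- function(a) cbind(a$x, a$y, a$z)

struct_chains <- function(s) unique(s$atoms$chain)

# Residue-level summary of one chain, in file order.
chain_residues <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  key <- res_key(a)
  idx <- !duplicated(key)
  data.frame(resno = a$resno[idx], ins = a$ins[idx], resid = a$resid[idx],
             key = key[idx], stringsAsFactors = FALSE)
}

# Chain classification: nucleotide if >= 50% of classifiable residues are
# nucleotides, peptide if any peptide residue dominates, else nonpolymer.
chain_types <- function(s, dict = ccd_dictionary()) {
  out <- character(0)
  for (ch in struct_chains(s)) {
    res <- chain_residues(s, ch)
    ty <- ccd_type(dict, res$resid)
    n_nuc <- sum(ty == "nucleotide", na.rm = TRUE)
    n_pep <- sum(ty == "peptide", na.rm = TRUE)
    out[ch] <- if (n_nuc + n_pep == 0) "nonpolymer"
               else if (n_nuc >= (n_nuc + n_pep) / 2) "nucleotide"
               else "peptide"
  }
  out
}

derive_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- c("MG", "ZN", "FE", "SE", "CL", "BR", "NA", "MN", "CA")
  ifelse(nm %in% two & nchar(gsub("[^A-Za-z0-9']", "", atom_name)) <= 2,
         nm, substr(nm, 1, 1))
}

# ---------------------------------------------------------------- readers --

#' Read a structure from PDBx/mmCIF or legacy PDB
#'
#' Chains are typed from mmCIF entity annotation when present, otherwise by
#' residue-name heuristics. For files with alternate conformations the
#' highest-occupancy conformer is kept (ties: first alphabetically); for
#' multi-model PDB files only the first model is used.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @param extract_ligands collect nonpolymer dictionary components as ligands
#'   (removing them from the polymer atom table).
#' @param dict chemical component dictionary, see [ccd_dictionary()].
#' @return a `struct` object.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           extract_ligands = FALSE, dict = ccd_dictionary()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  s <- if (format == "mmcif") read_mmcif(path) else read_pdb_file(path)
  if (extract_ligands) s <- split_out_ligands(s, dict)
  s
}

read_pdb_file <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- derive_element(a$elety[bad])
  atoms <- data.frame(chain = as.character(a$chain),
                      resno = as.integer(a$resno),
                      ins = ifelse(is.na(a$insert), "", as.character(a$insert)),
                      resid = trimws(a$resid), atom = trimws(a$elety),
                      elem = toupper(trimws(elem)),
                      x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      het = a$type == "HETATM", stringsAsFactors = FALSE)
  alt <- ifelse(is.na(a$alt), "", as.character(a$alt))
  atoms <- resolve_altloc(atoms, alt)
  new_struct(atoms, source_format = "pdb")
}

# keep highest-occupancy altloc per (residue, atom name); tie: alphabetical
resolve_altloc <- function(atoms, alt) {
  if (all(alt == "")) return(atoms)
  key <- paste(res_key(atoms), atoms$atom)
  ord <- order(key, -atoms$occ, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(res_key(atoms), atoms$atom)), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

# minimal mmCIF reader: atom_site plus entity/entity_poly categories
read_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cats <- parse_cif_categories(lines, path)
  as <- cats[["atom_site"]]
  if (is.null(as)) stop("cannot parse mmCIF file '", path,
                        "': no _atom_site records", call. = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(as)) return(as[[nm]])
    NULL
  }
  chain <- pick("auth_asym_id", "label_asym_id")
  resno <- pick("auth_seq_id", "label_seq_id")
  ins <- pick("pdbx_PDB_ins_code")
  ins <- if (is.null(ins)) "" else ifelse(ins %in% c("?", "."), "", ins)
  elem <- pick("type_symbol")
  atom <- gsub('"', "", pick("label_atom_id", "auth_atom_id"))
  if (is.null(elem)) elem <- derive_element(atom)
  occ <- pick("occupancy")
  alt <- pick("label_alt_id")
  alt <- if (is.null(alt)) "" else ifelse(alt %in% c("?", "."), "", alt)
  atoms <- data.frame(chain = chain, resno = as.integer(resno), ins = ins,
                      resid = pick("auth_comp_id", "label_comp_id"),
                      atom = atom, elem = toupper(elem),
                      x = as.numeric(pick("Cartn_x")),
                      y = as.numeric(pick("Cartn_y")),
                      z = as.numeric(pick("Cartn_z")),
                      occ = if (is.null(occ)) 1 else as.numeric(occ),
                      het = pick("group_PDB") %||% "ATOM" != "ATOM",
                      stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms, alt)
  entities <- NULL
  ent_id <- pick("label_entity_id")
  if (!is.null(ent_id)) {
    entities <- unique(data.frame(chain = chain, entity_id = ent_id,
                                  stringsAsFactors = FALSE))
    ent <- cats[["entity"]]
    entities$entity_type <-
      if (!is.null(ent)) ent$type[match(entities$entity_id, ent$id)]
      else NA_character_
    ep <- cats[["entity_poly"]]
    entities$seq <- if (!is.null(ep))
      gsub("[\n; ]", "", ep$pdbx_seq_one_letter_code_can[
        match(entities$entity_id, ep$entity_id)])
    else NA_character_
  }
  new_struct(atoms, entities = entities, source_format = "mmcif")
}

# Parses loop_ and key-value mmCIF categories into named lists of columns.
parse_cif_categories <- function(lines, path = "<input>") {
  lines <- lines[!grepl("^\\s*#", lines)]
  cats <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (ln == "loop_") {
      items <- character(0)
      i <- i + 1
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        items <- c(items, trimws(lines[i]))
        i <- i + 1
      }
      rows <- list()
      while (i <= n && !grepl("^(loop_|_|data_|#)", trimws(lines[i])) &&
             nzchar(trimws(lines[i]))) {
        rows[[length(rows) + 1L]] <- cif_tokens(lines[i])
        i <- i + 1
      }
      if (length(items)) {
        vals <- unlist(rows, use.names = FALSE)
        if (length(vals) %% length(items) != 0)
          stop("malformed mmCIF loop in '", path, "' near item ", items[1],
               call. = FALSE)
        m <- matrix(vals, ncol = length(items), byrow = TRUE)
        cat_name <- sub("^_([^.]+)\\..*$", "\\1", items[1])
        cols <- sub("^_[^.]+\\.", "", items)
        dat <- setNames(lapply(seq_along(cols), function(j) m[, j]), cols)
        cats[[cat_name]] <- if (is.null(cats[[cat_name]])) dat
          else Map(c, cats[[cat_name]], dat)
      }
    } else if (grepl("^_[^.]+\\.", ln)) {
      cat_name <- sub("^_([^.]+)\\..*$", "\\1", ln)
      key <- sub("^_[^.]+\\.(\\S+).*$", "\\1", ln)
      val <- sub("^\\S+\\s*", "", ln)
      if (!nzchar(val) && i < n) { i <- i + 1; val <- trimws(lines[i]) }
      val <- gsub("^['\"]|['\"]$", "", val)
      cats[[cat_name]][[key]] <- c(cats[[cat_name]][[key]], val)
      i <- i + 1
    } else i <- i + 1
  }
  cats
}

cif_tokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

# Move nonpolymer dictionary components from the atom table into ligands.
split_out_ligands <- function(s, dict) {
  a <- s$atoms
  ty <- ccd_type(dict, a$resid)
  is_lig <- !is.na(ty) & ty == "nonpolymer"
  if (!is.null(s$entities) && "entity_type" %in% names(s$entities)) {
    nonpoly <- s$entities$chain[!is.na(s$entities$entity_type) &
                                  s$entities$entity_type != "polymer"]
    is_lig <- is_lig | a$chain %in% nonpoly
  }
  lig_atoms <- a[is_lig, , drop = FALSE]
  ligs <- s$ligands
  if (nrow(lig_atoms)) {
    for (k in unique(res_key(lig_atoms))) {
      la <- lig_atoms[res_key(lig_atoms) == k, , drop = FALSE]
      la <- la[la$elem != "H", , drop = FALSE]
      code <- la$resid[1]
      bonds <- ligand_bonds_for(la, code, dict)
      ligs[[length(ligs) + 1L]] <-
        new_ligand(name = paste0(code, ":", la$chain[1], ".", la$resno[1]),
                   atoms = la[, c("atom", "elem", "x", "y", "z")],
                   bonds = bonds$bonds, source = bonds$source)
    }
  }
  s$atoms <- a[!is_lig, , drop = FALSE]
  s$ligands <- ligs
  s
}

# -------------------------------------------------------------- cleanup ----

#' Polymer cleanup applied before scoring
#'
#' Removes hydrogens, terminal OXT atoms and atoms whose names are not in the
#' component dictionary; replaces nonstandard residues with their parent
#' residue (e.g. SEP to SER) when `replace_nonstandard` is on (atoms absent
#' from the parent are dropped); removes residues without a dictionary entry;
#' and drops short polymer chains (fewer than 6 residues for peptides, fewer
#' than 4 for nucleotides). Cleanup is total and idempotent; removals are
#' recorded in the `cleanup_log` attribute.
#'
#' @param s a `struct`.
#' @param dict chemical component dictionary.
#' @param replace_nonstandard replace nonstandard residues by their parents
#'   (used for polymer scores; ligand-score receptors keep them).
#' @return cleaned `struct` with attribute `cleanup_log`.
#' @export
cleanup_polymer <- function(s, dict = ccd_dictionary(),
                            replace_nonstandard = TRUE) {
  a <- s$atoms
  log <- character(0)
  drop <- a$elem == "H" | a$atom == "OXT"
  if (any(drop)) log <- c(log, sprintf("removed %d hydrogen/OXT atoms", sum(drop)))
  a <- a[!drop, , drop = FALSE]
  keep <- rep(TRUE, nrow(a))
  key <- res_key(a)
  for (k in unique(key)) {
    idx <- which(key == k)
    code <- a$resid[idx[1]]
    comp <- ccd_comp(dict, code)
    if (is.null(comp) || comp$type == "nonpolymer") {
      keep[idx] <- FALSE
      log <- c(log, sprintf("removed residue %s (%s): no polymer dictionary entry",
                            k, code))
      next
    }
    parent <- ccd_parent(dict, code)
    if (!is.null(parent) && replace_nonstandard) {
      a$resid[idx] <- parent
      allowed <- ccd_atoms(dict, parent)
      log <- c(log, sprintf("replaced %s by parent %s in %s", code, parent, k))
    } else allowed <- ccd_atoms(dict, code)
    bad <- idx[!(a$atom[idx] %in% allowed)]
    if (length(bad)) {
      keep[bad] <- FALSE
      log <- c(log, sprintf("removed %d unknown-named atoms from %s",
                            length(bad), k))
    }
  }
  a <- a[keep, , drop = FALSE]
  s2 <- new_struct(a, entities = s$entities, ligands = s$ligands,
                   source_format = s$source_format)
  ty <- chain_types(s2, dict)
  for (ch in names(ty)) {
    nres <- nrow(chain_residues(s2, ch))
    min_len <- if (ty[ch] == "nucleotide") 4L else 6L
    if (ty[ch] != "nonpolymer" && nres < min_len) {
      s2$atoms <- s2$atoms[s2$atoms$chain != ch, , drop = FALSE]
      log <- c(log, sprintf("dropped short %s chain %s (%d residues)",
                            ty[ch], ch, nres))
    }
  }
  attr(s2, "cleanup_log") <- log
  s2
}

#' One-letter sequence of a polymer chain
#'
#' Residues without a dictionary one-letter code become `X` (peptides) or
#' `N` (nucleotides); length is preserved.
#'
#' @param s a `struct`; @param chain chain identifier.
#' @param dict chemical component dictionary.
#' @return character scalar.
#' @export
extract_sequence <- function(s, chain, dict = ccd_dictionary()) {
  ty <- chain_types(s, dict)[chain]
  if (is.na(ty) || ty == "nonpolymer")
    stop("chain '", chain, "' is not a polymer chain", call. = FALSE)
  res <- chain_residues(s, chain)
  one <- ccd_one_letter(dict, res$resid)
  one[is.na(one) | !nzchar(one)] <- if (ty == "nucleotide") "N" else "X"
  paste(one, collapse = "")
}

# -------------------------------------------------------------- writers ----

#' Write a structure in legacy PDB format (fixture writer)
#' @param s a `struct`; @param path output file.
#' @export
write_structure_pdb <- function(s, path) {
  a <- s$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in struct_chains(s)) {
    ai <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      serial <- serial + 1L
      nm <- ai$atom[i]
      nm_fmt <- if (nchar(nm) <= 3) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(ai$het[i], "HETATM", "ATOM"), serial, nm_fmt, "",
        ai$resid[i], ch, ai$resno[i],
        ifelse(nzchar(ai$ins[i]), ai$ins[i], " "),
        ai$x[i], ai$y[i], ai$z[i], ai$occ[i], 0, ai$elem[i]))
    }
    lines <- c(lines, "TER")
  }
  li <- 0L
  for (lg in s$ligands) {
    li <- li + 1L
    la <- lg$atoms
    for (i in seq_len(nrow(la))) {
      serial <- serial + 1L
      nm <- la$atom[i]
      nm_fmt <- if (nchar(nm) <= 3) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        "HETATM", serial, nm_fmt, "", substr(sub(":.*", "", lg$name), 1, 3),
        "z", li, " ", la$x[i], la$y[i], la$z[i], 1, 0, la$elem[i]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a structure in PDBx/mmCIF format (fixture writer)
#'
#' Emits `atom_site` plus `entity`/`entity_poly` categories. Entity ids are
#' taken from `s$entities` when present, otherwise one entity per chain.
#'
#' @param s a `struct`; @param path output file.
#' @param dict dictionary used to type chains.
#' @export
write_structure_mmcif <- function(s, path, dict = ccd_dictionary()) {
  a <- s$atoms
  ents <- s$entities
  if (is.null(ents)) {
    ch <- struct_chains(s)
    ty <- chain_types(s, dict)
    ents <- data.frame(chain = ch, entity_id = as.character(seq_along(ch)),
                       entity_type = ifelse(ty[ch] == "nonpolymer",
                                            "non-polymer", "polymer"),
                       seq = vapply(ch, function(cc)
                         if (ty[cc] == "nonpolymer") NA_character_
                         else extract_sequence(s, cc, dict), ""),
                       stringsAsFactors = FALSE)
  }
  out <- c("data_qsbench", "#", "loop_", "_entity.id", "_entity.type")
  ue <- ents[!duplicated(ents$entity_id), , drop = FALSE]
  out <- c(out, sprintf("%s %s", ue$entity_id,
                        ue$entity_type %||% "polymer"))
  poly <- ue[!is.na(ue$seq) & nzchar(ue$seq), , drop = FALSE]
  if (nrow(poly)) {
    out <- c(out, "#", "loop_", "_entity_poly.entity_id",
             "_entity_poly.pdbx_seq_one_letter_code_can",
             sprintf("%s %s", poly$entity_id, poly$seq))
  }
  out <- c(out, "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.auth_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy")
  ent_of <- setNames(ents$entity_id, ents$chain)
  lig_rows <- character(0)
  n_poly <- nrow(a)
  rows <- sprintf('%s %d %s "%s" %s %s %s %d %d %s %s %s %.3f %.3f %.3f %.2f',
                  ifelse(a$het, "HETATM", "ATOM"), seq_len(max(n_poly, 0)),
                  a$elem, a$atom, a$resid, a$chain,
                  ifelse(is.na(ent_of[a$chain]), ".", ent_of[a$chain]),
                  a$resno, a$resno,
                  ifelse(nzchar(a$ins), a$ins, "?"), a$resid, a$chain,
                  a$x, a$y, a$z, a$occ)
  k <- n_poly
  lig_ent <- max(suppressWarnings(as.integer(ue$entity_id)), 0, na.rm = TRUE)
  lig_chain_pool <- setdiff(c(letters, paste0("z", 1:99)), struct_chains(s))
  li <- 0
  for (lg in s$ligands) {
    li <- li + 1
    lig_ent <- lig_ent + 1
    lch <- lig_chain_pool[li]
    code <- substr(sub(":.*", "", lg$name), 1, 3)
    la <- lg$atoms
    for (i in seq_len(nrow(la))) {
      k <- k + 1
      lig_rows <- c(lig_rows, sprintf(
        'HETATM %d %s "%s" %s %s %d 1 1 ? %s %s %.3f %.3f %.3f 1.00',
        k, la$elem[i], la$atom[i], code, lch, lig_ent, code, lch,
        la$x[i], la$y[i], la$z[i]))
    }
    out <- c(out[seq_len(which(out == "_entity.type"))],
             sprintf("%d non-polymer", lig_ent),
             out[-seq_len(which(out == "_entity.type"))])
  }
  writeLines(c(out, rows, lig_rows, "#"), path)
  invisible(path)
}
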