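.qsbench_cache <- new.env(parent = emptyenv())

#' Chemical component dictionary subset
#'
#' Loads the bundled component dictionary (atom names, elements, bonds and
#' parent-residue codes for standard amino acids, RNA/DNA nucleotides, a few
#' modified residues and fixture compounds). A different dictionary can be
#' supplied as a directory containing `components.tsv`, `atoms.tsv` and
#' `bonds.tsv` with the same columns.
#'
#' @param path directory with the dictionary tables; default: bundled subset.
#' @return object of class `chem_dict` with elements `comps`, `atoms`,
#'   `bonds` (data frames).
#' @export
ccd_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    key <- "ccd_default"
    if (!is.null(.qsbench_cache[[key]])) return(.qsbench_cache[[key]])
    path <- system.file("extdata", "ccd", package = "qsbench")
  } else key <- NULL
  read1 <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                         header = TRUE, quote = "",
                                         stringsAsFactors = FALSE)
  dict <- structure(list(comps = read1("components.tsv"),
                         atoms = read1("atoms.tsv"),
                         bonds = read1("bonds.tsv")),
                    class = "chem_dict")
  dict$atom_sets <- split(dict$atoms$atom, dict$atoms$comp)
  if (!is.null(key)) .qsbench_cache[[key]] <- dict
  dict
}

ccd_comp <- function(dict, code) {
  i <- match(code, dict$comps$comp)
  if (is.na(i)) NULL else dict$comps[i, ]
}

ccd_type <- function(dict, codes) {
  dict$comps$type[match(codes, dict$comps$comp)]
}

ccd_one_letter <- function(dict, codes) {
  dict$comps$one_letter[match(codes, dict$comps$comp)]
}

ccd_parent <- function(dict, code) {
  p <- dict$comps$parent[match(code, dict$comps$comp)]
  if (length(p) == 0 || is.na(p) || !nzchar(p)) NULL else p
}

ccd_atoms <- function(dict, code) dict$atom_sets[[code]]

ccd_bonds <- function(dict, code) {
  b <- dict$bonds[dict$bonds$comp == code, , drop = FALSE]
  if (nrow(b) == 0) NULL else b[, c("atom1", "atom2")]
}

# Covalent radii (A) used for the clash criterion and the last-resort
# van-der-Waals bond heuristic.
covalent_radius <- function(elem) {
  r <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10, SE = 1.17,
         MG = 1.41, ZN = 1.22, FE = 1.24, H = 0.37)
  out <- r[toupper(elem)]
  out[is.na(out)] <- 0.9
  unname(out)
}

vdw_radius <- function(elem) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
         MG = 1.73, ZN = 1.39, FE = 1.52, H = 1.10)
  out <- r[toupper(elem)]
  out[is.na(out)] <- 1.7
  unname(out)
}
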