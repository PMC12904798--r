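# NUC44-style nucleotide substitution matrix (match 5 / mismatch -4,
# N scored as ambiguity), embedded as data; U scores as T.
nuc44_matrix <- function() {
  ab <- c("A", "C", "G", "T", "U", "N")
  m <- matrix(-4, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- 5
  m["T", "U"] <- m["U", "T"] <- 5
  m["N", ] <- m[, "N"] <- -2
  m["N", "N"] <- -1
  m
}

blosum62_matrix <- function() {
  if (is.null(.qsbench_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .qsbench_cache$blosum62 <- e$BLOSUM62
  }
  .qsbench_cache$blosum62
}

#' Alignment parameters for chain grouping and mapping
#'
#' @param mode `"sequence"` (Needleman-Wunsch global alignment) or
#'   `"residue_number"` (pair residues with equal author numbers, for
#'   CASP/CAMEO-style inputs numbered per target sequence).
#' @param seqid_cluster_threshold identity for grouping reference chains.
#' @param seqid_assign_threshold identity for model-to-group assignment;
#'   `NULL` removes the threshold (forces assignment to the best group).
#' @param min_len_peptide,min_len_nucleotide minimum chain lengths considered.
#' @param gap_open_peptide,gap_extend_peptide,gap_open_nucleotide,gap_extend_nucleotide
#'   gap penalties (costs, BLOSUM62 / NUC44 conventions).
#' @return a list of class `aln_params`.
#' @export
alignment_params <- function(mode = c("sequence", "residue_number"),
                             seqid_cluster_threshold = 0.95,
                             seqid_assign_threshold = 0.70,
                             min_len_peptide = 6L,
                             min_len_nucleotide = 4L,
                             gap_open_peptide = 11, gap_extend_peptide = 1,
                             gap_open_nucleotide = 5, gap_extend_nucleotide = 2) {
  structure(list(mode = match.arg(mode),
                 seqid_cluster_threshold = seqid_cluster_threshold,
                 seqid_assign_threshold = seqid_assign_threshold,
                 min_len_peptide = min_len_peptide,
                 min_len_nucleotide = min_len_nucleotide,
                 gap_open_peptide = gap_open_peptide,
                 gap_extend_peptide = gap_extend_peptide,
                 gap_open_nucleotide = gap_open_nucleotide,
                 gap_extend_nucleotide = gap_extend_nucleotide),
            class = "aln_params")
}

#' Global pairwise alignment with sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62 for peptides, an embedded
#' NUC44-style matrix for nucleotides). Identity is the fraction of identical
#' columns among aligned (non-gap) column pairs. In `residue_number` mode
#' residues are paired by equal author numbers instead and the alignment step
#' is skipped; `num_a`/`num_b` must then be supplied.
#'
#' @param a,b one-letter sequences.
#' @param chain_type `"peptide"` or `"nucleotide"`; both sequences must share it.
#' @param params [alignment_params()].
#' @param num_a,num_b residue-number keys, for `residue_number` mode.
#' @return list with `a_idx`, `b_idx` (paired 1-based positions), `identity`.
#' @export
align_pair <- function(a, b, chain_type = "peptide",
                       params = alignment_params(),
                       num_a = NULL, num_b = NULL) {
  stopifnot(nzchar(a), nzchar(b))
  if (params$mode == "residue_number") {
    stopifnot(!is.null(num_a), !is.null(num_b))
    common <- intersect(num_a, num_b)
    ai <- match(common, num_a)
    bi <- match(common, num_b)
    ca <- strsplit(a, "")[[1]][ai]
    cb <- strsplit(b, "")[[1]][bi]
    id <- if (length(ai)) mean(ca == cb) else 0
    return(list(a_idx = ai, b_idx = bi, identity = id))
  }
  if (chain_type == "nucleotide") {
    sm <- nuc44_matrix()
    go <- params$gap_open_nucleotide; ge <- params$gap_extend_nucleotide
  } else {
    sm <- blosum62_matrix()
    go <- params$gap_open_peptide; ge <- params$gap_extend_peptide
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = sm, gapOpening = go, gapExtension = ge)
  ga <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  id <- if (any(both)) mean(ga[both] == gb[both]) else 0
  list(a_idx = ia[both], b_idx = ib[both], identity = id)
}

# cached sequence-mode alignment between two chains of two structures
chain_correspondence <- function(ref, mdl, rch, mch, params, dict,
                                 cache = NULL) {
  key <- paste("corr", rch, mch, params$mode)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  rres <- chain_residues(ref, rch)
  mres <- chain_residues(mdl, mch)
  ty <- chain_types(ref, dict)[rch]
  if (params$mode == "residue_number") {
    al <- align_pair(extract_sequence(ref, rch, dict),
                     extract_sequence(mdl, mch, dict),
                     ty, params,
                     num_a = paste(rres$resno, rres$ins),
                     num_b = paste(mres$resno, mres$ins))
  } else {
    al <- align_pair(extract_sequence(ref, rch, dict),
                     extract_sequence(mdl, mch, dict), ty, params)
  }
  out <- list(ref_idx = al$a_idx, mdl_idx = al$b_idx,
              ref_key = rres$key[al$a_idx], mdl_key = mres$key[al$b_idx],
              identity = al$identity)
  if (!is.null(cache)) cache[[key]] <- out
  out
}
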