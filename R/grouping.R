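#' Group chemically equivalent reference chains
#'
#' Protein and nucleotide chains are grouped separately. With mmCIF entity
#' records available, entities define the groups directly (entities with an
#' identical canonical sequence are merged, which rescues chains covering
#' nonoverlapping fragments of one target); otherwise chains are clustered by
#' single-linkage over the pairwise sequence-identity graph at the 95%
#' threshold. The longest chain is the group representative (ties:
#' lexicographically smallest chain id).
#'
#' @param ref cleaned reference `struct`.
#' @param params [alignment_params()].
#' @param dict chemical component dictionary.
#' @return list of `chain_group`s: `id`, `chain_type`, `ref_chains`,
#'   `rep_seq`, `mdl_chains` (empty until [assign_model_chains()]).
#' @export
group_reference_chains <- function(ref, params = alignment_params(),
                                   dict = ccd_dictionary()) {
  ty <- chain_types(ref, dict)
  chains <- names(ty)[ty %in% c("peptide", "nucleotide")]
  min_len <- function(ch) if (ty[ch] == "nucleotide")
    params$min_len_nucleotide else params$min_len_peptide
  chains <- chains[vapply(chains, function(ch)
    nrow(chain_residues(ref, ch)) >= min_len(ch), TRUE)]
  if (!length(chains)) return(list())
  seqs <- vapply(chains, function(ch) extract_sequence(ref, ch, dict), "")

  ent <- ref$entities
  use_entities <- !is.null(ent) && all(chains %in% ent$chain) &&
    "seq" %in% names(ent) && !anyNA(ent$seq[match(chains, ent$chain)])
  if (use_entities) {
    eid <- ent$entity_id[match(chains, ent$chain)]
    eseq <- ent$seq[match(chains, ent$chain)]
    # merge entities sharing the same canonical sequence annotation
    grp_key <- eseq
    comp <- match(grp_key, unique(grp_key))
  } else {
    n <- length(chains)
    adj <- diag(TRUE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      if (ty[chains[i]] != ty[chains[j]]) next
      rres <- chain_residues(ref, chains[i])
      mres <- chain_residues(ref, chains[j])
      al <- align_pair(seqs[i], seqs[j], ty[chains[i]], params,
                       num_a = paste(rres$resno, rres$ins),
                       num_b = paste(mres$resno, mres$ins))
      adj[i, j] <- adj[j, i] <- al$identity >= params$seqid_cluster_threshold
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  }
  groups <- list()
  for (k in sort(unique(comp))) {
    member <- chains[comp == k]
    lens <- vapply(member, function(ch) nrow(chain_residues(ref, ch)), 0L)
    rep_chain <- member[order(-lens, member)][1]
    rep_seq <- if (use_entities) {
      es <- ent$seq[match(rep_chain, ent$chain)]
      if (!is.na(es) && nzchar(es)) es else seqs[[rep_chain]]
    } else seqs[[rep_chain]]
    groups[[length(groups) + 1L]] <- structure(
      list(id = sprintf("grp%02d", length(groups) + 1L),
           chain_type = unname(ty[rep_chain]),
           ref_chains = sort(member), rep_chain = rep_chain,
           rep_seq = rep_seq, mdl_chains = character(0)),
      class = "chain_group")
  }
  groups
}

#' Assign model chains to reference chain groups
#'
#' Each model polymer chain is assigned to the group whose representative
#' sequence gives the highest identity, if that identity reaches
#' `identity_threshold` (default 70%, relaxed to allow homologs; `NULL`
#' removes the threshold and forces assignment). Chains below the threshold
#' are reported unmapped.
#'
#' @param mdl cleaned model `struct`.
#' @param groups from [group_reference_chains()].
#' @param params [alignment_params()].
#' @param identity_threshold fraction in (0,1] or `NULL`.
#' @param dict chemical component dictionary.
#' @return `grouping_result`: `groups` (with `mdl_chains` filled),
#'   `unmapped_model_chains`, `params`.
#' @export
assign_model_chains <- function(mdl, groups, params = alignment_params(),
                                identity_threshold = 0.70,
                                dict = ccd_dictionary()) {
  ty <- chain_types(mdl, dict)
  chains <- names(ty)[ty %in% c("peptide", "nucleotide")]
  min_len <- function(ch) if (ty[ch] == "nucleotide")
    params$min_len_nucleotide else params$min_len_peptide
  chains <- chains[vapply(chains, function(ch)
    nrow(chain_residues(mdl, ch)) >= min_len(ch), TRUE)]
  unmapped <- character(0)
  for (ch in chains) {
    best <- 0; best_g <- NA_integer_
    sq <- extract_sequence(mdl, ch, dict)
    mres <- chain_residues(mdl, ch)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      if (g$chain_type != ty[ch]) next
      al <- align_pair(g$rep_seq, sq, g$chain_type, params,
                       num_a = paste(seq_len(nchar(g$rep_seq)), ""),
                       num_b = paste(mres$resno, mres$ins))
      if (al$identity > best) { best <- al$identity; best_g <- gi }
    }
    ok <- !is.na(best_g) &&
      (is.null(identity_threshold) || best >= identity_threshold)
    if (ok) groups[[best_g]]$mdl_chains <-
        sort(c(groups[[best_g]]$mdl_chains, ch))
    else unmapped <- c(unmapped, ch)
  }
  structure(list(groups = groups, unmapped_model_chains = unmapped,
                 params = params),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  for (g in x$groups)
    cat(sprintf("%s (%s): ref [%s] <- mdl [%s]\n", g$id, g$chain_type,
                paste(g$ref_chains, collapse = ","),
                paste(g$mdl_chains, collapse = ",")))
  if (length(x$unmapped_model_chains))
    cat("unmapped model chains:",
        paste(x$unmapped_model_chains, collapse = ","), "\n")
  invisible(x)
}
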