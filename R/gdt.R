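# Mapped representative-position pairs (CA for peptides, C3' for
# nucleotides) across all mapped chains, plus the total number of reference
# representative positions (the GDT denominator, so incomplete models are
# penalised).
mapped_rep_pairs <- function(ref, mdl, mapping, params_aln, dict) {
  pairs <- if (is.character(mapping)) mapping else mapping$pairs
  pairs <- pairs[!is.na(pairs)]
  cache <- new.env(parent = emptyenv())
  ty <- chain_types(ref, dict)
  ra <- ref$atoms
  rep_sel <- ra$atom == backbone_rep_atom(ty[ra$chain]) &
    ty[ra$chain] %in% c("peptide", "nucleotide")
  n_ref <- sum(rep_sel)
  ma <- mdl$atoms
  mkey <- paste(res_key(ma), ma$atom)
  X <- NULL; Y <- NULL
  for (rch in sort(names(pairs))) {
    if (!rch %in% ra$chain || !pairs[[rch]] %in% ma$chain) next
    corr <- chain_correspondence(ref, mdl, rch, pairs[[rch]], params_aln,
                                 dict, cache)
    rep_at <- backbone_rep_atom(ty[rch])
    ri <- match(paste(corr$ref_key, rep_at), paste(res_key(ra), ra$atom))
    mi <- match(paste(corr$mdl_key, rep_at), mkey)
    ok <- !is.na(ri) & !is.na(mi)
    X <- rbind(X, coords(ra)[ri[ok], , drop = FALSE])
    Y <- rbind(Y, coords(ma)[mi[ok], , drop = FALSE])
  }
  list(X = X, Y = Y, n_ref = n_ref)
}

#' GDT: global distance test (TS and HA)
#'
#' Fraction of reference representative positions superposable onto the
#' model within distance thresholds. Starting sets are sliding windows of
#' sizes 7, 9, 12, 24 and 48 over the mapped positions (each applied at up
#' to `max_windows` equidistant placements); each start is iteratively
#' refined (superpose on the set, re-collect all pairs within the threshold)
#' until the set stops changing, and the largest set observed is kept.
#' GDT_TS averages thresholds 1, 2, 4, 8 A; GDT_HA 0.5, 1, 2, 4 A; both on
#' a 0-1 scale.
#'
#' @param ref,mdl cleaned structures.
#' @param mapping chain mapping (for oligomers, from [qsmapr()]).
#' @param window_sizes sliding-window sizes (clamped to the chain length).
#' @param max_windows maximum placements per window size.
#' @param params_aln [alignment_params()]; @param dict dictionary.
#' @return list `gdt_ts`, `gdt_ha`, `fractions` (named per threshold).
#' @export
gdt <- function(ref, mdl, mapping, window_sizes = c(7, 9, 12, 24, 48),
                max_windows = 1000, params_aln = alignment_params(),
                dict = ccd_dictionary()) {
  mp <- mapped_rep_pairs(ref, mdl, mapping, params_aln, dict)
  n <- if (is.null(mp$X)) 0 else nrow(mp$X)
  if (n < 3)
    return(list(gdt_ts = NA_real_, gdt_ha = NA_real_,
                reason = "fewer than 3 mapped positions"))
  thresholds <- c(0.5, 1, 2, 4, 8)
  best <- stats::setNames(numeric(length(thresholds)),
                          as.character(thresholds))
  sizes <- unique(pmin(window_sizes, n))
  sizes <- sizes[sizes >= 3]
  for (t in thresholds) {
    largest <- 0L
    for (w in sizes) {
      n_start <- n - w + 1L
      starts <- if (n_start > max_windows)
        unique(floor(seq(1, n_start, length.out = max_windows)))
      else seq_len(n_start)
      for (s0 in starts) {
        set <- s0:(s0 + w - 1L)
        for (it in 1:20) {
          if (length(set) < 3) break
          fit <- kabsch(mp$X[set, , drop = FALSE],
                        mp$Y[set, , drop = FALSE])
          yt <- fit$transform(mp$Y)
          newset <- which(sqrt(rowSums((mp$X - yt)^2)) <= t)
          largest <- max(largest, length(newset))
          if (identical(newset, set)) break
          set <- newset
        }
      }
    }
    best[as.character(t)] <- largest / mp$n_ref
  }
  list(gdt_ts = mean(best[c("1", "2", "4", "8")]),
       gdt_ha = mean(best[c("0.5", "1", "2", "4")]),
       fractions = best)
}

#' Backbone RMSD after Kabsch superposition
#'
#' Minimal RMSD over all mapped representative positions (CA for peptides,
#' C3' for nucleotides); for oligomers the chain mapping should come from
#' [qsmapr()].
#'
#' @inheritParams gdt
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(ref, mdl, mapping,
                          params_aln = alignment_params(),
                          dict = ccd_dictionary()) {
  mp <- mapped_rep_pairs(ref, mdl, mapping, params_aln, dict)
  n <- if (is.null(mp$X)) 0 else nrow(mp$X)
  if (n < 3) stop("fewer than 3 mapped representative positions",
                  call. = FALSE)
  kabsch(mp$X, mp$Y)$rmsd
}
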