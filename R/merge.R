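#' Merge two validated alignments block-wise by SP score
#'
#' Both alignments are stripped of all-gap columns, recoded as binary
#' masks, and partitioned into block pairs of identical sequence
#' fragments at the cutting sites. For each block pair the block with the
#' higher SP score is kept (ties keep the first operand's block), and the
#' winners are concatenated in cut order. Because the SP objective is
#' additive over column partitions, the result's SP score is at least
#' `max(sp(a1), sp(a2))`.
#'
#' @param a1,a2 [msa()] objects validated against the same reference.
#' @param scheme A [scoring_scheme()].
#' @return A list with elements `alignment` (the merged [msa()]) and
#'   `report` (a data frame of per-block provenance: interval bounds,
#'   `sp1`, `sp2`, `winner`, `tie`).
#' @export
merge_pair <- function(a1, a2, scheme = scoring_scheme()) {
  if (length(a1$rows) != length(a2$rows)) {
    stop("alignments have different sequence counts", call. = FALSE)
  }
  a1 <- strip_all_gap_columns(a1)
  a2 <- strip_all_gap_columns(a2)
  cuts <- find_cutting_sites(recode(a1), recode(a2))
  blocks <- partition_blocks(a1, a2, cuts, scheme)
  winner <- ifelse(blocks$sp1 >= blocks$sp2, 1L, 2L)
  tie <- blocks$sp1 == blocks$sp2
  pieces <- character(nrow(blocks))
  rows <- character(length(a1$rows))
  for (i in seq_along(rows)) {
    for (b in seq_len(nrow(blocks))) {
      pieces[b] <- if (winner[b] == 1L) {
        substr(a1$rows[i], blocks$start1[b] + 1L, blocks$end1[b])
      } else {
        substr(a2$rows[i], blocks$start2[b] + 1L, blocks$end2[b])
      }
    }
    rows[i] <- paste(pieces, collapse = "")
  }
  merged <- strip_all_gap_columns(msa(a1$ids, rows))
  report <- cbind(blocks, winner = winner, tie = tie)
  list(alignment = merged, report = report)
}

#' Merge a validated ensemble in descending SP order
#'
#' The accepted alignments are sorted by whole-alignment SP score, ties
#' keeping input order, and folded with [merge_pair()]: the two best are
#' merged first, then the running result is merged with the next best,
#' for m - 1 pairwise merges in total. The merge order is fixed once from
#' the initial SP scores. A single accepted alignment is returned
#' unchanged with a warning (nothing to merge).
#'
#' @param validated A `validation_report` from [validate_ensemble()], or
#'   a plain list of [msa()] objects (SP scores are then computed here).
#' @param scheme A [scoring_scheme()].
#' @return A list with elements `alignment` (the final merged [msa()]),
#'   `order` (labels in merge order), `input_sp` (named input SP scores),
#'   `sp` (final SP score) and `steps` (per-merge block reports).
#' @export
merge_ensemble <- function(validated, scheme = scoring_scheme()) {
  if (inherits(validated, "validation_report")) {
    entries <- validated$accepted
  } else {
    if (length(validated) == 0L) stop("empty alignment list", call. = FALSE)
    entries <- lapply(seq_along(validated), function(i) {
      list(label = paste0("aln", i), alignment = validated[[i]],
           sp = sp_score(validated[[i]], scheme = scheme))
    })
  }
  sp_in <- vapply(entries, `[[`, numeric(1), "sp")
  labels <- vapply(entries, `[[`, character(1), "label")
  names(sp_in) <- labels
  ord <- order(-sp_in)
  if (length(entries) == 1L) {
    warning("only one validated alignment; returning it unmerged")
    a <- strip_all_gap_columns(entries[[1L]]$alignment)
    return(list(alignment = a, order = labels, input_sp = sp_in,
                sp = sp_score(a, scheme = scheme), steps = list()))
  }
  steps <- vector("list", length(entries) - 1L)
  current <- entries[[ord[1L]]]$alignment
  for (k in seq.int(2L, length(entries))) {
    res <- merge_pair(current, entries[[ord[k]]]$alignment, scheme)
    current <- res$alignment
    steps[[k - 1L]] <- res$report
  }
  list(alignment = current, order = labels[ord], input_sp = sp_in,
       sp = sp_score(current, scheme = scheme), steps = steps)
}
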