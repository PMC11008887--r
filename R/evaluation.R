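# Residue-ordinal matrix: entry [i, c] is the 1-based ordinal of the
# residue of sequence i placed in column c, or NA for a gap cell.
residue_ordinals <- function(a) {
  m <- aln_matrix(a)
  gap <- m == "-" | m == "."
  ord <- row_cumsum(!gap)
  ord[gap] <- NA_integer_
  ord
}

# Set of aligned residue pairs, encoded as strings "i:j:oi:oj" for each
# unordered row pair (i < j) whose residues oi, oj share a column.
residue_pair_keys <- function(ord) {
  n <- nrow(ord)
  keys <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- !is.na(ord[i, ]) & !is.na(ord[j, ])
      k <- k + 1L
      keys[[k]] <- paste(i, j, ord[i, both], ord[j, both], sep = ":")
    }
  }
  unlist(keys, use.names = FALSE)
}

check_same_sequences <- function(test, ref) {
  if (length(test$rows) != length(ref$rows)) {
    stop("test and reference have different sequence counts", call. = FALSE)
  }
  if (!identical(toupper(sanitize(degap(test$rows))),
                 toupper(sanitize(degap(ref$rows))))) {
    stop("test and reference do not degap to the same sequences ",
         "in the same order", call. = FALSE)
  }
}

#' Q score: fraction of reference residue pairs reproduced
#'
#' Every pair of residues placed in the same column of the reference is
#' counted; the score is the fraction of those pairs that also share a
#' column in the test alignment. 1 means the test reproduces every
#' aligned residue pair of the reference.
#'
#' @param test,ref [msa()] objects over the same sequences in the same
#'   order (case-insensitive; gap placement may differ).
#' @return A number in \[0, 1\].
#' @examples
#' ref <- msa(c("a", "b"), c("A-C", "AGC"))
#' test <- msa(c("a", "b"), c("-AC", "AGC"))
#' q_score(test, ref)  # 0.5
#' @export
q_score <- function(test, ref) {
  check_same_sequences(test, ref)
  ref_keys <- residue_pair_keys(residue_ordinals(ref))
  if (length(ref_keys) == 0L) {
    stop("reference alignment has no aligned residue pairs", call. = FALSE)
  }
  test_keys <- residue_pair_keys(residue_ordinals(test))
  sum(ref_keys %in% test_keys) / length(ref_keys)
}

#' TC score: fraction of reference columns reproduced
#'
#' A reference column is counted as correctly aligned when its full
#' residue-ordinal signature (which residue of each sequence, or a gap,
#' occupies the column) appears as a column of the test alignment. The
#' denominator is the total number of reference columns.
#'
#' @inheritParams q_score
#' @return A number in \[0, 1\].
#' @examples
#' ref <- msa(c("a", "b"), c("A-C", "AGC"))
#' test <- msa(c("a", "b"), c("-AC", "AGC"))
#' tc_score(test, ref)  # 1/3
#' @export
tc_score <- function(test, ref) {
  check_same_sequences(test, ref)
  if (ref$width == 0L) stop("reference alignment has no columns", call. = FALSE)
  sig <- function(ord) {
    ord[is.na(ord)] <- -1L
    apply(ord, 2L, paste, collapse = ",")
  }
  ref_sig <- sig(residue_ordinals(ref))
  test_sig <- sig(residue_ordinals(test))
  sum(ref_sig %in% test_sig) / length(ref_sig)
}
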