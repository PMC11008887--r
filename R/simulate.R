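DNA_BASES <- c("A", "C", "G", "T")

#' Generate a related reference sequence set
#'
#' Draws a random DNA ancestor and derives each sequence from it by
#' independent per-site substitutions and short indels (1-3 bases). This
#' produces a family of mutually related sequences of (possibly) unequal
#' lengths, sufficient to exercise validation, partitioning, merging and
#' the quality metrics. It makes no attempt at phylogenetic realism: all
#' sequences are siblings of one ancestor with site-independent
#' mutations.
#'
#' @param n_sequences Number of sequences (default 10).
#' @param length_range Ancestor length is drawn uniformly from this
#'   inclusive range (default `c(100, 200)`).
#' @param substitution_rate Per-site substitution probability per
#'   sequence (default 0.05).
#' @param indel_rate Per-site probability of starting an indel (default
#'   0.02); each indel inserts or deletes 1-3 bases with equal
#'   probability.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A [seq_set()] with ids `seq1`, `seq2`, ...
#' @export
generate_reference <- function(n_sequences = 10L,
                               length_range = c(100L, 200L),
                               substitution_rate = 0.05,
                               indel_rate = 0.02,
                               seed = 1L) {
  if (n_sequences < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  len <- sample(length_range[1L]:length_range[2L], 1L)
  ancestor <- sample(DNA_BASES, len, replace = TRUE)
  seqs <- character(n_sequences)
  for (i in seq_len(n_sequences)) {
    s <- ancestor
    sub_at <- which(stats::runif(length(s)) < substitution_rate)
    for (p in sub_at) {
      s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    }
    # indels scanned right-to-left so positions stay valid
    indel_at <- which(stats::runif(length(s)) < indel_rate)
    for (p in rev(indel_at)) {
      size <- sample(1:3, 1L)
      if (stats::runif(1L) < 0.5) {       # deletion
        drop <- p:min(p + size - 1L, length(s))
        if (length(drop) < length(s)) s <- s[-drop]
      } else {                            # insertion
        ins <- sample(DNA_BASES, size, replace = TRUE)
        s <- append(s, ins, after = p)
      }
    }
    if (length(s) == 0L) s <- sample(DNA_BASES, 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seq_set(paste0("seq", seq_len(n_sequences)), seqs)
}

# Left-flush alignment: residues first, trailing gaps up to max length.
# For identical equal-length sequences this is the trivial gapless one.
left_flush_alignment <- function(r) {
  w <- max(nchar(r$residues))
  msa(r$ids, paste0(r$residues, strrep("-", w - nchar(r$residues))))
}

# Random gap placement: choose, per row, a sorted subset of columns to
# hold the residues. Always degaps back to r.
random_placement_alignment <- function(r, width) {
  rows <- vapply(r$residues, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    row <- rep("-", width)
    row[sort(sample.int(width, length(chars)))] <- chars
    paste(row, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  msa(r$ids, rows)
}

#' Generate an ensemble of distinct valid alignments
#'
#' Emulates running several aligners on one sequence set: every returned
#' alignment degaps row-wise to exactly `r`, but the gap placements
#' differ. The first alignment is the left-flush layout (for identical
#' equal-length sequences this is the trivial gapless alignment); the
#' others are either locally jittered copies of it or random gap
#' placements, chosen per alignment.
#'
#' @param r A [seq_set()].
#' @param k Number of alignments (default 5).
#' @param seed Integer seed.
#' @param extra_width_frac The random-placement width is the maximum
#'   sequence length inflated by up to this fraction (default 0.2).
#' @return A list of `k` [msa()] objects, each consistent with `r`.
#' @export
generate_ensemble <- function(r, k = 5L, seed = 1L, extra_width_frac = 0.2) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  set.seed(seed)
  maxlen <- max(nchar(r$residues))
  out <- vector("list", k)
  out[[1L]] <- left_flush_alignment(r)
  for (i in seq_len(k)[-1L]) {
    if (stats::runif(1L) < 0.5) {
      out[[i]] <- corrupt_alignment(out[[1L]],
                                    n_moves = sample(10:60, 1L),
                                    seed = sample.int(.Machine$integer.max, 1L))
    } else {
      width <- maxlen + sample.int(max(1L, round(maxlen * extra_width_frac)), 1L)
      out[[i]] <- random_placement_alignment(r, width)
    }
  }
  out
}

#' Perturb an alignment by local gap shifts
#'
#' Applies up to `n_moves` random swaps of a gap with an adjacent
#' residue. Each swap moves a gap one position within a row, so residue
#' order is preserved and the result still degaps to the same sequences.
#' Used to create controlled degradations for metric tests: more moves
#' means, on average, fewer residue pairs shared with the original.
#'
#' @param a An [msa()].
#' @param n_moves Number of attempted local shifts (0 returns `a`).
#' @param seed Integer seed.
#' @return A perturbed [msa()] consistent with the same sequences.
#' @export
corrupt_alignment <- function(a, n_moves, seed = 1L) {
  if (n_moves == 0L) return(a)
  set.seed(seed)
  m <- aln_matrix(a)
  n <- nrow(m); w <- ncol(m)
  if (w < 2L) return(a)
  for (mv in seq_len(n_moves)) {
    i <- sample.int(n, 1L)
    gap <- m[i, ] == "-"
    # boundaries where a gap neighbours a residue
    edge <- which(gap[-w] != gap[-1L])
    if (length(edge) == 0L) next
    p <- edge[sample.int(length(edge), 1L)]
    tmp <- m[i, p]; m[i, p] <- m[i, p + 1L]; m[i, p + 1L] <- tmp
  }
  msa_from_matrix(a$ids, m)
}
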