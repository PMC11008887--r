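#' Sum-of-pairs scoring scheme
#'
#' The SP objective scores each unordered pair of characters in a column:
#' two identical letters score `match`, two different letters `mismatch`,
#' a letter against a gap `letter_vs_gap`, and two gaps `other`. The
#' defaults (1, -1, -2, 0) are the conventional nucleic-acid values used
#' throughout this package. Letter comparison is case-insensitive; IUPAC
#' ambiguity codes are treated as ordinary letters.
#'
#' @param match Score for two identical letters (default 1).
#' @param mismatch Score for two different letters (default -1).
#' @param letter_vs_gap Score for a letter paired with a gap (default -2).
#' @param other Score for two gaps (default 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L,
                           letter_vs_gap = -2L, other = 0L) {
  s <- list(match = as.numeric(match), mismatch = as.numeric(mismatch),
            letter_vs_gap = as.numeric(letter_vs_gap),
            other = as.numeric(other))
  structure(s, class = "scoring_scheme")
}

is_gap_char <- function(x) x == "-" | x == "."

#' Score a single aligned character pair
#'
#' @param x,y Single characters, each a letter or a gap.
#' @param scheme A [scoring_scheme()].
#' @return The pair score; symmetric in `x` and `y`.
#' @examples
#' pair_score("A", "A")  #  1
#' pair_score("A", "G")  # -1
#' pair_score("A", "-")  # -2
#' pair_score("-", "-")  #  0
#' @export
pair_score <- function(x, y, scheme = scoring_scheme()) {
  gx <- is_gap_char(x); gy <- is_gap_char(y)
  if (gx && gy) return(scheme$other)
  if (gx || gy) return(scheme$letter_vs_gap)
  if (toupper(x) == toupper(y)) scheme$match else scheme$mismatch
}

#' Score one alignment column
#'
#' Sum of [pair_score()] over all unordered pairs of rows in the column.
#'
#' @param column Character vector of the column's cells (length >= 2).
#' @param scheme A [scoring_scheme()].
#' @return The column score (integer-valued).
#' @export
column_score <- function(column, scheme = scoring_scheme()) {
  n <- length(column)
  if (n < 2L) stop("a column needs at least 2 rows", call. = FALSE)
  s <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s <- s + pair_score(column[i], column[j], scheme)
    }
  }
  s
}

# Vectorised per-column SP scores for a character matrix (rows = sequences).
# Counts letters per column instead of enumerating pairs: with n letters
# and g gaps in a column, letter-letter pairs split into matches
# (sum over letters of C(count, 2)) and mismatches, letter-gap pairs are
# n * g, and gap-gap pairs are C(g, 2). Exact integer arithmetic in doubles.
column_scores_matrix <- function(m, scheme = scoring_scheme()) {
  nrows <- nrow(m)
  up <- toupper(m)
  gap <- up == "-" | up == "."
  n_gap <- colSums(gap)
  n_let <- nrows - n_gap
  matches <- numeric(ncol(m))
  up[gap] <- NA_character_
  for (letter in unique(up[!gap])) {
    cnt <- colSums(up == letter, na.rm = TRUE)
    matches <- matches + cnt * (cnt - 1) / 2
  }
  let_pairs <- n_let * (n_let - 1) / 2
  gap_pairs <- n_gap * (n_gap - 1) / 2
  matches * scheme$match +
    (let_pairs - matches) * scheme$mismatch +
    n_let * n_gap * scheme$letter_vs_gap +
    gap_pairs * scheme$other
}

#' Sum-of-pairs score of an alignment or column interval
#'
#' The SP score is the sum of [column_score()] over the requested
#' columns. It is additive over any partition of the columns, which is
#' what makes block-wise merging dominate: the merged alignment's SP is
#' the sum of the per-block maxima.
#'
#' @param a An [msa()].
#' @param start,end Column interval, 0-based half-open (`start`
#'   inclusive, `end` exclusive). Defaults to the whole alignment. A
#'   zero-width interval scores 0.
#' @param scheme A [scoring_scheme()].
#' @return The SP score (integer-valued numeric).
#' @examples
#' sp_score(msa(c("a", "b"), c("AC-", "A-G")))  # -3
#' @export
sp_score <- function(a, start = 0L, end = a$width, scheme = scoring_scheme()) {
  if (start < 0L || end > a$width || start > end) {
    stop("invalid column interval [", start, ", ", end, ")", call. = FALSE)
  }
  if (start == end) return(0)
  m <- aln_matrix(a)
  sum(column_scores_matrix(m[, (start + 1L):end, drop = FALSE], scheme))
}

#' Average sum-of-pairs score
#'
#' The whole-alignment SP score divided by the number of unordered
#' sequence pairs, C(N, 2). Unlike the raw SP score it is comparable
#' across alignments with different numbers of sequences.
#'
#' @param a An [msa()] with at least 2 rows.
#' @param scheme A [scoring_scheme()].
#' @return The aSP score (numeric).
#' @export
asp_score <- function(a, scheme = scoring_scheme()) {
  n <- length(a$rows)
  if (n < 2L) stop("aSP needs at least 2 sequences", call. = FALSE)
  sp_score(a, scheme = scheme) / (n * (n - 1) / 2)
}
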