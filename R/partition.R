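#' Recode an alignment as a gap/residue binary mask
#'
#' Gaps map to 0 and every other character to 1. After recoding, base
#' composition is irrelevant: only the gap-insertion pattern matters for
#' finding compatible cut positions between two alignments.
#'
#' @param a An [msa()].
#' @return An integer matrix of 0/1 with one row per sequence and one
#'   column per alignment column.
#' @export
recode <- function(a) {
  m <- aln_matrix(a)
  mask <- matrix(1L, nrow = nrow(m), ncol = ncol(m))
  mask[m == "-" | m == "."] <- 0L
  mask
}

#' Drop columns consisting entirely of gaps
#'
#' All-gap columns carry no alignment information, score 0 under the SP
#' objective, and make cut positions non-unique (the cumulative residue
#' counts plateau across them), so every alignment is normalised this way
#' before partitioning.
#'
#' @param a An [msa()].
#' @return The alignment without its all-gap columns. Dropping every
#'   column is an error.
#' @export
strip_all_gap_columns <- function(a) {
  m <- aln_matrix(a)
  keep <- colSums(m != "-" & m != ".") > 0L
  if (!any(keep)) stop("alignment consists only of gap columns", call. = FALSE)
  if (all(keep)) return(a)
  msa_from_matrix(a$ids, m[, keep, drop = FALSE])
}

#' Find cutting sites between two binary masks
#'
#' Two pointers traverse the masks column by column, each maintaining a
#' "pace" vector: the per-sequence cumulative count of residues (1s)
#' scanned so far. The active pointer advances until some component of
#' its pace strictly exceeds the other's, at which point the pointers
#' swap; whenever the two pace vectors are exactly equal, the current
#' pair of positions is recorded as a cutting site. Each column is
#' visited exactly once, so the scan is linear in the total width.
#'
#' Both masks must have the same per-sequence residue totals (guaranteed
#' for alignments validated against the same reference) and no all-gap
#' columns (see [strip_all_gap_columns()]).
#'
#' @param m1,m2 Integer 0/1 matrices from [recode()].
#' @return An object of class `cut_sites`: an integer matrix with columns
#'   `c1`, `c2` giving, for each cutting site, the number of columns of
#'   each mask consumed so far (equivalently the 0-based half-open end of
#'   the block in each alignment). The last row is always
#'   `(ncol(m1), ncol(m2))`. Attribute `advances` counts total pointer
#'   advances (always `ncol(m1) + ncol(m2)`).
#' @export
find_cutting_sites <- function(m1, m2) {
  if (nrow(m1) != nrow(m2)) {
    stop("masks have different sequence counts", call. = FALSE)
  }
  tot1 <- rowSums(m1); tot2 <- rowSums(m2)
  if (!identical(tot1, tot2)) {
    stop("masks have unequal per-sequence residue totals; ",
         "inputs were not validated against the same reference",
         call. = FALSE)
  }
  w1 <- ncol(m1); w2 <- ncol(m2)
  n <- nrow(m1)
  pace1 <- numeric(n); pace2 <- numeric(n)
  pos1 <- 0L; pos2 <- 0L
  active <- 1L
  advances <- 0L
  c1 <- integer(0L); c2 <- integer(0L)
  while (pos1 < w1 || pos2 < w2) {
    if (active == 1L && pos1 >= w1) active <- 2L
    if (active == 2L && pos2 >= w2) active <- 1L
    if (active == 1L) {
      pos1 <- pos1 + 1L
      pace1 <- pace1 + m1[, pos1]
      advances <- advances + 1L
      if (all(pace1 == pace2)) {
        c1 <- c(c1, pos1); c2 <- c(c2, pos2)
      } else if (any(pace1 > pace2)) {
        active <- 2L
      }
    } else {
      pos2 <- pos2 + 1L
      pace2 <- pace2 + m2[, pos2]
      advances <- advances + 1L
      if (all(pace1 == pace2)) {
        c1 <- c(c1, pos1); c2 <- c(c2, pos2)
      } else if (any(pace2 > pace1)) {
        active <- 1L
      }
    }
  }
  structure(cbind(c1 = c1, c2 = c2), advances = advances,
            class = c("cut_sites", "matrix", "array"))
}

#' Partition two alignments into block pairs at the cutting sites
#'
#' Consecutive cutting sites delimit half-open column intervals in each
#' alignment; corresponding intervals hold identical sequence fragments
#' (same residues per row, possibly different gap placement) and form a
#' block pair. Each block is annotated with its SP score.
#'
#' @param a1,a2 [msa()] objects (validated, all-gap columns stripped).
#' @param cuts Output of [find_cutting_sites()] on their masks.
#' @param scheme A [scoring_scheme()].
#' @return A data frame with one row per block pair: `start1`, `end1`,
#'   `start2`, `end2` (0-based half-open intervals), `sp1`, `sp2`.
#' @export
partition_blocks <- function(a1, a2, cuts, scheme = scoring_scheme()) {
  nb <- nrow(cuts)
  if (nb == 0L) stop("no cutting sites; masks are incompatible", call. = FALSE)
  start1 <- c(0L, cuts[-nb, "c1"]); end1 <- cuts[, "c1"]
  start2 <- c(0L, cuts[-nb, "c2"]); end2 <- cuts[, "c2"]
  # per-row residue counts must match across each block pair
  mask1 <- recode(a1); mask2 <- recode(a2)
  cum1 <- cbind(0, row_cumsum(mask1))
  cum2 <- cbind(0, row_cumsum(mask2))
  for (b in seq_len(nb)) {
    r1 <- cum1[, end1[b] + 1L] - cum1[, start1[b] + 1L]
    r2 <- cum2[, end2[b] + 1L] - cum2[, start2[b] + 1L]
    if (!all(r1 == r2)) {
      stop("internal error: block ", b, " fragments differ between inputs",
           call. = FALSE)
    }
  }
  sp1 <- vapply(seq_len(nb), function(b)
    sp_score(a1, start1[b], end1[b], scheme), numeric(1))
  sp2 <- vapply(seq_len(nb), function(b)
    sp_score(a2, start2[b], end2[b], scheme), numeric(1))
  data.frame(start1 = start1, end1 = end1, start2 = start2, end2 = end2,
             sp1 = sp1, sp2 = sp2)
}
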