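# Independent brute-force oracles, deliberately written along different
# code paths than the package implementations they check.

# SP score by explicit double loop over all unordered row pairs.
brute_sp <- function(a, scheme = scoring_scheme()) {
  m <- toupper(aln_matrix(a))
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      x <- m[i, ]; y <- m[j, ]
      gx <- x == "-"; gy <- y == "-"
      total <- total +
        sum(!gx & !gy & x == y) * scheme$match +
        sum(!gx & !gy & x != y) * scheme$mismatch +
        sum(xor(gx, gy)) * scheme$letter_vs_gap +
        sum(gx & gy) * scheme$other
    }
  }
  total
}

# Cutting sites by full enumeration: compute every prefix pace vector of
# both masks and intersect. After all-gap-column stripping each prefix
# vector is distinct within a mask, so matching by key is well defined.
brute_cuts <- function(m1, m2) {
  key <- function(m) {
    cs <- apply(m, 1L, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L) else cs <- t(cs)
    apply(cs, 2L, paste, collapse = ",")
  }
  k1 <- key(m1); k2 <- key(m2)
  common <- intersect(k1, k2)
  pairs <- cbind(c1 = match(common, k1), c2 = match(common, k2))
  pairs[order(pairs[, "c1"]), , drop = FALSE]
}

# Q score by direct lookup: for each residue pair aligned in the
# reference, locate where those residue ordinals sit in the test and
# check they share a column.
brute_q <- function(test, ref) {
  ord_cols <- function(a) {
    m <- aln_matrix(a)
    gap <- m == "-" | m == "."
    # cols[[i]][o] = column of a holding residue o of sequence i
    lapply(seq_len(nrow(m)), function(i) which(!gap[i, ]))
  }
  rc <- ord_cols(ref); tc <- ord_cols(test)
  n <- length(rc)
  hits <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # ordinal of each sequence's residue in every ref column, NA if gap
      oi <- match(seq_len(ref$width), rc[[i]])
      oj <- match(seq_len(ref$width), rc[[j]])
      both <- !is.na(oi) & !is.na(oj)
      total <- total + sum(both)
      for (col in which(both)) {
        if (tc[[i]][oi[col]] == tc[[j]][oj[col]]) hits <- hits + 1L
      }
    }
  }
  hits / total
}

random_mask <- function(n, w) {
  repeat {
    m <- matrix(sample(0:1, n * w, replace = TRUE, prob = c(0.3, 0.7)),
                nrow = n)
    keep <- colSums(m) > 0L
    m <- m[, keep, drop = FALSE]
    if (ncol(m) >= 1L && all(rowSums(m) > 0L)) return(m)
  }
}

# Second mask with the same per-row residue totals as `m`, random widths.
matched_mask <- function(m, extra = 5L) {
  n <- nrow(m)
  tot <- rowSums(m)
  w <- max(tot) + sample.int(extra, 1L)
  out <- matrix(0L, n, w)
  for (i in seq_len(n)) out[i, sort(sample.int(w, tot[i]))] <- 1L
  keep <- colSums(out) > 0L
  out[, keep, drop = FALSE]
}

random_alignment <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- seq_set(paste0("s", seq_len(n)),
               vapply(seq_len(n),
                      function(i) paste(sample(c("A", "C", "G", "T"),
                                              len, replace = TRUE),
                                        collapse = ""),
                      character(1)))
  random_placement_alignment_test(r, len + sample.int(20L, 1L))
}

# local copy of the random-placement layout for tests that need an
# arbitrary valid alignment without going through the generator API
random_placement_alignment_test <- function(r, width) {
  rows <- vapply(r$residues, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    row <- rep("-", width)
    row[sort(sample.int(width, length(chars)))] <- chars
    paste(row, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  msa(r$ids, rows)
}
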