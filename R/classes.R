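GAP_CHARS <- c("-", ".")

#' Construct a sequence set
#'
#' A `seq_set` holds the ordered, unaligned reference sequences. The order
#' of the records is canonical: every validated alignment is reordered to
#' it and the merged output inherits it.
#'
#' @param ids Character vector of record identifiers.
#' @param residues Character vector of sequences (letters only after
#'   [sanitize()]); same length as `ids`.
#' @return An object of class `seq_set` with elements `ids` and `residues`.
#' @examples
#' r <- seq_set(c("s1", "s2"), c("ACGT", "ACG"))
#' length(r)
#' @export
seq_set <- function(ids, residues) {
  ids <- as.character(ids)
  residues <- as.character(residues)
  if (length(ids) != length(residues)) {
    stop("`ids` and `residues` must have the same length", call. = FALSE)
  }
  if (length(ids) < 2L) {
    stop("a sequence set needs at least 2 records", call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("empty sequence in records: ",
         paste(ids[!nzchar(residues)], collapse = ", "), call. = FALSE)
  }
  structure(list(ids = ids, residues = residues), class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$ids)

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", length(x), " sequences, lengths ",
      min(nchar(x$residues)), "-", max(nchar(x$residues)), "\n", sep = "")
  invisible(x)
}

#' Construct a multiple sequence alignment
#'
#' An `msa` is a set of equal-width rows over letters and the gap
#' character. Input gap dialects `-` and `.` are both accepted; `.` is
#' normalised to `-` on construction. Letter case is preserved.
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of gapped rows, all the same width.
#' @return An object of class `msa` with elements `ids`, `rows`, `width`.
#' @examples
#' a <- msa(c("s1", "s2"), c("AC-", "A-G"))
#' a$width
#' @export
msa <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- as.character(rows)
  if (length(ids) != length(rows)) {
    stop("`ids` and `rows` must have the same length", call. = FALSE)
  }
  if (length(rows) == 0L) stop("alignment has no rows", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row widths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  if (widths[1L] < 1L) stop("alignment width must be >= 1", call. = FALSE)
  rows <- gsub(".", "-", rows, fixed = TRUE)
  structure(list(ids = ids, rows = rows, width = widths[1L]), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$rows), " sequences x ", x$width, " columns\n", sep = "")
  invisible(x)
}

# Character matrix view (rows = sequences), used by scoring and metrics.
aln_matrix <- function(a) {
  matrix(unlist(strsplit(a$rows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(a$rows), ncol = a$width, byrow = TRUE)
}

# Rebuild an msa from a character matrix.
msa_from_matrix <- function(ids, m) {
  msa(ids, apply(m, 1L, paste, collapse = ""))
}

# Row-wise cumulative sums, shape-preserving (t(apply(...)) mis-orients
# single-column matrices).
row_cumsum <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) out[i, ] <- cumsum(m[i, ])
  out
}

#' Remove gap characters from a row
#'
#' @param x Character vector of gapped rows.
#' @return The rows with all `-` and `.` characters removed.
#' @export
degap <- function(x) gsub("[-.]", "", x)
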