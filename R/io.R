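#' Remove non-letter characters from a sequence
#'
#' Everything except the 26 uppercase and lowercase ASCII letters is
#' dropped; the relative order of surviving characters is preserved. This
#' is applied to both the reference sequences and the degapped alignment
#' rows before any comparison, so stray symbols (`*`, digits, whitespace)
#' never cause a spurious consistency failure.
#'
#' @param residues Character vector of raw sequences.
#' @return Character vector with only ASCII letters retained.
#' @examples
#' sanitize("AC*G")   # "ACG"
#' sanitize("A-C.G")  # "ACG"
#' @export
sanitize <- function(residues) {
  gsub("[^A-Za-z]", "", residues)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param is_alignment If `TRUE`, the records are interpreted as the rows
#'   of a multiple alignment and must all have equal width.
#' @return A [seq_set()] (default) or an [msa()] (`is_alignment = TRUE`).
#' @export
read_fasta <- function(path, is_alignment = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  seqs <- as.character(recs)
  if (is_alignment) {
    msa(ids, seqs)
  } else {
    cleaned <- sanitize(seqs)
    if (any(!nzchar(cleaned))) {
      stop("sequence(s) with no letter characters in ", path, ": ",
           paste(ids[!nzchar(cleaned)], collapse = ", "), call. = FALSE)
    }
    seq_set(ids, cleaned)
  }
}

#' Write sequences or an alignment to FASTA
#'
#' Rows are wrapped at `width` characters per line; gaps are emitted as
#' `-`. Reading the file back yields an identical object.
#'
#' @param x A [seq_set()] or [msa()].
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "seq_set")) {
    ids <- x$ids; seqs <- x$residues
  } else if (inherits(x, "msa")) {
    ids <- x$ids; seqs <- x$rows
  } else {
    stop("`x` must be a seq_set or msa", call. = FALSE)
  }
  if (length(seqs) == 0L) stop("nothing to write", call. = FALSE)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Reorder alignment rows to match the reference order
#'
#' Rows are matched to reference records by identifier when the two sets
#' of identifiers correspond one-to-one; otherwise by sanitized ungapped
#' content (case-insensitive). Duplicate identical sequences are assigned
#' greedily in first-occurrence order, so the permutation is stable.
#'
#' @param a An [msa()].
#' @param r A [seq_set()] with the same number of sequences.
#' @return The alignment with rows permuted into `r`'s order.
#' @export
reorder_alignment <- function(a, r) {
  n <- length(r)
  if (length(a$rows) != n) {
    stop("alignment has ", length(a$rows), " rows but reference has ", n,
         " records", call. = FALSE)
  }
  if (!anyDuplicated(a$ids) && !anyDuplicated(r$ids) &&
      setequal(a$ids, r$ids)) {
    perm <- match(r$ids, a$ids)
  } else {
    key_a <- toupper(sanitize(degap(a$rows)))
    key_r <- toupper(sanitize(r$residues))
    perm <- integer(n)
    used <- logical(n)
    for (i in seq_len(n)) {
      j <- which(key_a == key_r[i] & !used)
      if (length(j) == 0L) {
        stop("no alignment row matches reference record '", r$ids[i], "'",
             call. = FALSE)
      }
      perm[i] <- j[1L]
      used[j[1L]] <- TRUE
    }
  }
  msa(r$ids, a$rows[perm])
}

#' Check that an alignment degaps to the reference
#'
#' Row `i` must satisfy `sanitize(degap(row)) == sanitize(reference)` up
#' to letter case. The alignment is assumed already reordered to `r`'s
#' order (see [reorder_alignment()]).
#'
#' @param a An [msa()].
#' @param r A [seq_set()].
#' @return `TRUE`, or `FALSE` with attribute `reason` describing the
#'   first mismatch.
#' @export
check_consistency <- function(a, r) {
  if (length(a$rows) != length(r)) {
    return(structure(FALSE, reason = sprintf(
      "row count %d differs from reference count %d",
      length(a$rows), length(r))))
  }
  got <- toupper(sanitize(degap(a$rows)))
  want <- toupper(sanitize(r$residues))
  bad <- which(got != want)
  if (length(bad) > 0L) {
    return(structure(FALSE, reason = sprintf(
      "row %d ('%s') degaps to a different sequence than the reference",
      bad[1L], r$ids[bad[1L]])))
  }
  TRUE
}

#' Validate an ensemble of candidate alignments
#'
#' Each candidate is reordered to the reference order, checked for
#' row-wise consistency with the reference, and annotated with its whole-
#' alignment SP score. Inconsistent candidates are rejected with a
#' reason; at least one candidate must survive.
#'
#' @param alignments List of [msa()] candidates.
#' @param r The [seq_set()] reference.
#' @param labels Optional character labels (defaults to `aln1`, `aln2`, ...).
#' @param scheme A [scoring_scheme()].
#' @return A list of class `validation_report` with elements
#'   `accepted` (list of `list(label, alignment, sp)`) and
#'   `rejected` (list of `list(label, reason)`).
#' @export
validate_ensemble <- function(alignments, r, labels = NULL,
                              scheme = scoring_scheme()) {
  if (length(alignments) < 1L) stop("no candidate alignments", call. = FALSE)
  if (is.null(labels)) labels <- paste0("aln", seq_along(alignments))
  accepted <- list()
  rejected <- list()
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (length(a$rows) != length(r)) {
      rejected[[length(rejected) + 1L]] <- list(
        label = labels[i],
        reason = sprintf("row count %d differs from reference count %d",
                         length(a$rows), length(r)))
      next
    }
    a2 <- tryCatch(reorder_alignment(a, r), error = function(e) e)
    if (inherits(a2, "error")) {
      rejected[[length(rejected) + 1L]] <- list(label = labels[i],
                                                reason = conditionMessage(a2))
      next
    }
    ok <- check_consistency(a2, r)
    if (!isTRUE(ok)) {
      rejected[[length(rejected) + 1L]] <- list(label = labels[i],
                                                reason = attr(ok, "reason"))
      next
    }
    accepted[[length(accepted) + 1L]] <- list(
      label = labels[i], alignment = a2,
      sp = sp_score(a2, scheme = scheme))
  }
  if (length(accepted) == 0L) {
    stop("no candidate alignment is consistent with the reference; ",
         "nothing to merge", call. = FALSE)
  }
  structure(list(accepted = accepted, rejected = rejected),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> accepted ", length(x$accepted), ", rejected ",
      length(x$rejected), "\n", sep = "")
  for (a in x$accepted) cat("  + ", a$label, " (SP = ", a$sp, ")\n", sep = "")
  for (rj in x$rejected) cat("  - ", rj$label, ": ", rj$reason, "\n", sep = "")
  invisible(x)
}
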