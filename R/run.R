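#' Validate, merge and write an alignment ensemble
#'
#' End-to-end driver: reads the unaligned reference and the candidate
#' alignments from FASTA, validates the candidates (reorder to reference
#' order, sanitize, consistency check), merges the survivors block-wise
#' in descending SP order, and writes the merged alignment. Rejected
#' candidates are reported as warnings with their reasons; if no
#' candidate survives, the run fails.
#'
#' @param ref_path Path to the unaligned reference FASTA.
#' @param aln_paths Character vector of candidate alignment FASTA paths
#'   (at least one).
#' @param out_path Output path for the merged alignment FASTA.
#' @param scheme A [scoring_scheme()].
#' @param report_path Optional path for a tab-separated per-block merge
#'   report (step, block, widths, sp1, sp2, winner).
#' @param quiet Suppress informational messages (default `FALSE`).
#' @return Invisibly, a list with `alignment`, `validation` (the
#'   [validate_ensemble()] report) and `merge` (the [merge_ensemble()]
#'   result).
#' @export
run_merge <- function(ref_path, aln_paths, out_path,
                      scheme = scoring_scheme(), report_path = NULL,
                      quiet = FALSE) {
  if (length(aln_paths) < 1L) {
    stop("at least one candidate alignment is required", call. = FALSE)
  }
  r <- read_fasta(ref_path)
  alns <- lapply(aln_paths, read_fasta, is_alignment = TRUE)
  report <- validate_ensemble(alns, r, labels = basename(aln_paths),
                              scheme = scheme)
  for (rej in report$rejected) {
    warning("rejected ", rej$label, ": ", rej$reason, call. = FALSE)
  }
  if (!quiet) {
    message("validated ", length(report$accepted), " of ", length(alns),
            " candidate alignment(s)")
  }
  merged <- merge_ensemble(report, scheme = scheme)
  if (!quiet) {
    message("merge order: ", paste(merged$order, collapse = " > "),
            "; final SP = ", merged$sp)
  }
  write_fasta(merged$alignment, out_path)
  if (!is.null(report_path)) {
    steps <- merged$steps
    if (length(steps) > 0L) {
      tab <- do.call(rbind, lapply(seq_along(steps), function(s) {
        cbind(step = s, block = seq_len(nrow(steps[[s]])), steps[[s]])
      }))
    } else {
      tab <- data.frame(step = integer(0), block = integer(0))
    }
    utils::write.table(tab, report_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(list(alignment = merged$alignment, validation = report,
                 merge = merged))
}
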