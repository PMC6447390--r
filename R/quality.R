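#' Fraction of unknown residues in the central domain
#'
#' Assembly gaps (NNN runs) translate to `X`; the share of `X` within the
#' central repeat domain is the quantity the 15%/70% completeness thresholds
#' and the quality-code NNN bands are applied to.
#'
#' @param record A [protein_record()].
#' @param partition A [domain_partition()] tiling the record.
#' @return Fraction in \[0,1\]; `0` for an empty central span.
#' @export
central_unknown_fraction <- function(record, partition) {
  stopifnot(inherits(partition, "domain_partition"))
  if (partition$length != nchar(record$residues)) {
    stop("partition does not tile the record", call. = FALSE)
  }
  central <- span_residues(record, partition$central)
  n <- nchar(central)
  if (n == 0L) return(0)
  count_char(central, "X") / n
}

#' Classify sequence completeness (complete / partial / fragmentary)
#'
#' A sequence is *complete* when (1) both termini are free of unknown
#' residues, (2) at least three X-free tandem repeat units — operationalised
#' as detected X-free Gly-loops — are present in the central domain, and
#' (3) no more than 15% of the central domain is unknown. If (1) and (2)
#' hold but the central unknown fraction lies in (0.15, 0.70) the sequence
#' is *partial*; anything else is *fragmentary*.
#'
#' @param record A [protein_record()].
#' @param partition A [domain_partition()].
#' @param loops Loops detected on the central span with
#'   `exclude_loops_with_X = TRUE` (see [detect_gly_loops()]); computed
#'   automatically when `NULL`.
#' @return `"complete"`, `"partial"` or `"fragmentary"`.
#' @export
classify_completeness <- function(record, partition, loops = NULL) {
  if (is.null(loops)) {
    loops <- detect_gly_loops(span_residues(record, partition$central),
                              loop_config(exclude_loops_with_X = TRUE))
  }
  termini_clean <-
    count_char(span_residues(record, partition$n_term), "X") == 0L &&
    count_char(span_residues(record, partition$c_term), "X") == 0L
  frac <- central_unknown_fraction(record, partition)
  n_clean_loops <- if (is.null(loops)) 0L else nrow(loops)
  if (termini_clean && n_clean_loops >= 3L && frac <= 0.15) return("complete")
  if (termini_clean && n_clean_loops >= 3L && frac > 0.15 && frac < 0.70) {
    return("partial")
  }
  "fragmentary"
}

#' Assign the nine-level quality code
#'
#' Collapses structural defects and unknown-residue content into a single
#' code 1-9, first match wins:
#'
#' 9. gene evidence only — under 10% of the reference orthologue length;
#' 7. frameshift mutation(s);
#' 8. premature stop codon;
#' 6. start codon / N-terminal region absent;
#' 5. stop codon / C-terminal region absent;
#' otherwise a central-domain unknown band:
#' 1. 0% unknown and defect-free (fully complete);
#' 2. at most 15% unknown;
#' 3. 15.1%-75% unknown;
#' 4. above 75% unknown (including near-total gap content).
#'
#' The precedence among structural defects is this package's convention
#' (severity 9, 7, 8, 6, 5); published tables print one code per gene but do
#' not state a tie-break.
#'
#' @param record A [protein_record()].
#' @param partition A [domain_partition()].
#' @param flags A [defect_flags()] object for the underlying CDS.
#' @param reference_length Length (residues) of the reference orthologue
#'   (e.g. the chicken gene); must be positive.
#' @return Integer code in 1-9.
#' @export
assign_quality_code <- function(record, partition, flags = defect_flags(),
                                reference_length) {
  stopifnot(reference_length > 0)
  rel <- nchar(record$residues) / reference_length
  if (rel < 0.10) return(9L)
  if (isTRUE(flags$frameshift)) return(7L)
  if (isTRUE(flags$premature_stop)) return(8L)
  if (isTRUE(flags$missing_start)) return(6L)
  if (isTRUE(flags$missing_stop)) return(5L)
  frac <- central_unknown_fraction(record, partition)
  if (frac == 0) return(1L)
  if (frac <= 0.15) return(2L)
  if (frac <= 0.75) return(3L)
  4L
}

#' Full quality assessment of one record
#'
#' Convenience wrapper combining [classify_completeness()],
#' [assign_quality_code()] and [central_unknown_fraction()].
#'
#' @inheritParams assign_quality_code
#' @param loops Optional precomputed loops (see [classify_completeness()]).
#' @return A list of class `quality_assessment`: `completeness`, `code`,
#'   `central_unknown_fraction`, `flags`, `relative_length`.
#' @export
assess_quality <- function(record, partition, flags = defect_flags(),
                           reference_length, loops = NULL) {
  completeness <- classify_completeness(record, partition, loops)
  # a structurally defective gene is never complete, whatever its X content
  if (completeness == "complete" && any_defect(flags)) {
    completeness <- "fragmentary"
  }
  structure(list(
    completeness = completeness,
    code = assign_quality_code(record, partition, flags, reference_length),
    central_unknown_fraction = central_unknown_fraction(record, partition),
    flags = flags,
    relative_length = nchar(record$residues) / reference_length
  ), class = "quality_assessment")
}

#' @export
print.quality_assessment <- function(x, ...) {
  cat(sprintf("<quality_assessment> %s (code %d), central X %.1f%%\n",
              x$completeness, x$code, 100 * x$central_unknown_fraction))
  invisible(x)
}
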