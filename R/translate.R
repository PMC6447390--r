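STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a CDS with unknown-base (N) awareness
#'
#' Translates under the standard genetic code. Any codon containing at least
#' one `N` yields the unknown residue `X` — this is how assembly-gap NNN runs
#' propagate into protein space and ultimately drive the quality
#' classification. A trailing incomplete codon is ignored. Internal stop
#' codons are rendered as `*` in the returned string and flagged.
#'
#' Returned defect flags:
#' * `missing_start` — first codon is not `ATG`;
#' * `missing_stop` — last complete codon is not `TAA`/`TAG`/`TGA`;
#' * `premature_stop` — a stop codon occurs before the last complete codon;
#' * `frameshift` — `(length - frame_offset) %% 3 != 0`, the length-mod-3
#'   signature of an indel inside the coding span.
#'
#' @param cds A [cds_record()].
#' @return A list with `protein` (residue string, `X` and internal `*`
#'   allowed; the terminal stop is not emitted) and `flags`
#'   (a [defect_flags()] object).
#' @examples
#' translate_cds(cds_record("g", "ATGGGATAA"))$protein  # "MG"
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "cds_record"))
  bases <- substring(cds$bases, cds$frame_offset + 1L)
  n <- nchar(bases)
  if (n < 3L) stop("CDS '", cds$id, "': shorter than one codon", call. = FALSE)
  n_codons <- n %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_codons)
  codons <- substring(bases, starts, starts + 2L)

  aa <- ifelse(grepl("N", codons, fixed = TRUE),
               "X",
               unname(Biostrings::GENETIC_CODE[codons]))
  is_stop <- codons %in% STOP_CODONS

  flags <- defect_flags(
    missing_start = codons[1] != "ATG",
    missing_stop = !is_stop[n_codons],
    premature_stop = any(is_stop[-n_codons]),
    frameshift = (n %% 3L) != 0L
  )
  # drop a genuine terminal stop from the protein string
  if (is_stop[n_codons]) aa <- aa[-n_codons]
  list(protein = paste(aa, collapse = ""), flags = flags)
}
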