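#' Construct a protein record
#'
#' A `protein_record` is the basic unit of analysis: one loricrin-like protein
#' with a species code (5-letter style, e.g. `GALGA`), a gene label
#' (`LOR1`, `LOR2`, `LOR2B`, `LOR3`, `LOR3B` or `OTHER`), and residues over the
#' 20 standard amino acids plus `X` for unknown residues arising from assembly
#' gaps (NNN runs in the underlying genome).
#'
#' A single terminal `*` (stop) is stripped on construction; internal `*`
#' characters are rejected — translated sequences carrying internal stops stay
#' as plain strings with their defect flags until curated.
#'
#' @param id Unique sequence identifier.
#' @param residues Residue string over the 20 amino acids plus `X`.
#' @param species_code Species code, e.g. `"GALGA"`; may be `""`.
#' @param gene_label One of `LOR1`, `LOR2`, `LOR2B`, `LOR3`, `LOR3B`, `OTHER`.
#' @param source_note Optional free-text provenance (scaffold, coordinates).
#' @return An object of class `protein_record`.
#' @examples
#' protein_record("a", "GGSSGG", species_code = "GALGA", gene_label = "LOR1")
#' @export
protein_record <- function(id, residues, species_code = "",
                           gene_label = "OTHER", source_note = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  residues <- sub("\\*$", "", residues)
  if (!nzchar(residues)) {
    stop("protein record '", id, "': residues must be non-empty", call. = FALSE)
  }
  check_alphabet(residues, AA_ALPHABET_X, what = paste0("protein '", id, "'"))
  gene_label <- match.arg(gene_label, GENE_LABELS)
  structure(
    list(id = id, species_code = species_code, gene_label = gene_label,
         residues = residues, source_note = source_note),
    class = "protein_record"
  )
}

#' Construct a CDS record
#'
#' Nucleotide coding sequence over `A,C,G,T,N`; `N` marks unknown bases from
#' assembly gaps. `frame_offset` (0-2) is applied before translation.
#'
#' @param id Unique sequence identifier.
#' @param bases Base string over `A,C,G,T,N`.
#' @param frame_offset Integer 0-2; bases skipped before the first codon.
#' @return An object of class `cds_record`.
#' @examples
#' cds_record("g1", "ATGGGATAA")
#' @export
cds_record <- function(id, bases, frame_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(bases), length(bases) == 1L)
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  bases <- toupper(bases)
  check_alphabet(bases, NT_ALPHABET_N, what = paste0("CDS '", id, "'"))
  if (nchar(bases) - frame_offset < 3L) {
    stop("CDS '", id, "': fewer than one codon after frame offset",
         call. = FALSE)
  }
  structure(
    list(id = id, bases = bases, frame_offset = frame_offset),
    class = "cds_record"
  )
}

#' Structural defect flags for a coding sequence
#'
#' The four independently testable defects used by the quality classifier:
#' missing start codon, missing stop codon, premature internal stop, and a
#' frameshift detected as coding length not divisible by three.
#'
#' @param missing_start,missing_stop,premature_stop,frameshift Logical flags.
#' @return An object of class `defect_flags`.
#' @export
defect_flags <- function(missing_start = FALSE, missing_stop = FALSE,
                         premature_stop = FALSE, frameshift = FALSE) {
  out <- list(missing_start = isTRUE(missing_start),
              missing_stop = isTRUE(missing_stop),
              premature_stop = isTRUE(premature_stop),
              frameshift = isTRUE(frameshift))
  structure(out, class = "defect_flags")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s [%s %s] %d aa (%d X)\n",
              x$id,
              if (nzchar(x$species_code)) x$species_code else "?",
              x$gene_label,
              nchar(x$residues),
              count_char(x$residues, "X")))
  invisible(x)
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s %d nt (frame %d, %d N)\n",
              x$id, nchar(x$bases), x$frame_offset,
              count_char(x$bases, "N")))
  invisible(x)
}

#' @export
print.defect_flags <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  cat("<defect_flags>", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

# any(flag) helper used by the quality classifier
any_defect <- function(flags) {
  any(vapply(unclass(flags), isTRUE, logical(1)))
}

count_char <- function(x, ch) {
  lengths(regmatches(x, gregexpr(ch, x, fixed = TRUE)))
}

# validate a sequence string against an alphabet, reporting the first
# offending position (1-based) as the contract requires
check_alphabet <- function(x, alphabet, what = "sequence") {
  chars <- seq_chars(x)
  bad <- which(!(chars %in% alphabet))
  if (length(bad)) {
    stop(what, ": illegal character '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  invisible(TRUE)
}
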