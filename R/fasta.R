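#' Read protein or nucleotide FASTA
#'
#' Parses a FASTA file into a list of [protein_record()] or [cds_record()]
#' objects. Headers follow the `id|SPECIES|GENE` dialect: tokens after the
#' first are optional; an unrecognised or missing gene token maps to `OTHER`
#' and a missing species token to `""`. Sequences are uppercased. Protein
#' sequences must stay within the 20 amino acids plus `X`; nucleotide
#' sequences within `A,C,G,T,N`.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"` or `"nucleotide"`.
#' @return A named list of records (names = ids).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a|GALGA|LOR1", "GGSS"), tf)
#' read_fasta(tf, "protein")
#' @export
read_fasta <- function(path, kind = c("protein", "nucleotide")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  headers <- names(set)
  seqs <- unname(toupper(as.character(set)))
  ids <- vapply(strsplit(headers, "|", fixed = TRUE), `[[`, character(1), 1L)
  ids <- trimws(ids)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate id in ", path, ": '", dup[1], "'", call. = FALSE)
  }
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    tok <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    if (kind == "protein") {
      species <- if (length(tok) >= 2L) trimws(tok[2]) else ""
      gene <- if (length(tok) >= 3L) toupper(trimws(tok[3])) else "OTHER"
      if (!gene %in% GENE_LABELS) gene <- "OTHER"
      recs[[i]] <- protein_record(ids[i], seqs[i], species_code = species,
                                  gene_label = gene)
    } else {
      recs[[i]] <- cds_record(ids[i], seqs[i])
    }
  }
  names(recs) <- ids
  recs
}

#' Write records to FASTA
#'
#' Inverse of [read_fasta()]: protein records are written with
#' `id|SPECIES|GENE` headers so that a write/read round trip reproduces ids
#' and sequences exactly.
#'
#' @param records List of `protein_record` or `cds_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    if (inherits(r, "protein_record")) {
      c(paste0(">", r$id, "|", r$species_code, "|", r$gene_label), r$residues)
    } else {
      c(paste0(">", r$id), r$bases)
    }
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a flat table of records as TSV
#'
#' Rows are lists (or one-row data frames) sharing one field set; columns keep
#' declaration order of the first row. Doubles are rendered with the fixed
#' two-decimal convention used for loop-size averages (e.g. `11.44`); integers
#' and strings are written as-is.
#'
#' @param rows List of named lists, or a data frame.
#' @param path Output path.
#' @param fields Optional explicit column order; required to emit a
#'   header-only file from an empty list of rows.
#' @return `path`, invisibly.
#' @examples
#' write_table(list(list(id = "a", mean_size = 11.444999)), tempfile())
#' @export
write_table <- function(rows, path, fields = NULL) {
  if (is.data.frame(rows)) {
    if (is.null(fields)) fields <- names(rows)
    rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))
  }
  stopifnot(is.list(rows))
  if (length(rows) == 0L) {
    writeLines(if (is.null(fields)) character(0)
               else paste(fields, collapse = "\t"), path)
    return(invisible(path))
  }
  if (is.null(fields)) fields <- names(rows[[1]])
  if (is.null(fields) || any(!nzchar(fields))) {
    stop("rows must have named fields", call. = FALSE)
  }
  for (r in rows) {
    if (!identical(sort(names(r)), sort(fields))) {
      stop("heterogeneous rows: field sets differ", call. = FALSE)
    }
  }
  fmt1 <- function(v) {
    if (length(v) != 1L || is.na(v)) return("NA")
    if (is.double(v)) sprintf("%.2f", v) else as.character(v)
  }
  body <- vapply(rows, function(r) {
    paste(vapply(fields, function(f) fmt1(r[[f]]), character(1)),
          collapse = "\t")
  }, character(1))
  writeLines(c(paste(fields, collapse = "\t"), body), path)
  invisible(path)
}
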