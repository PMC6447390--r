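#' Residue and nucleotide alphabets
#'
#' Constants shared across the package: the 20 standard amino acids (in
#' conventional one-letter alphabetical order), the protein alphabet with the
#' unknown residue `X`, and the nucleotide alphabet with `N`.
#'
#' @format Character vectors of single letters.
#' @name alphabets
NULL

#' @rdname alphabets
#' @export
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname alphabets
#' @export
AA_ALPHABET_X <- c(AA_STANDARD, "X")

#' @rdname alphabets
#' @export
NT_ALPHABET_N <- c("A", "C", "G", "T", "N")

# split a sequence string into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# gene labels recognised in FASTA headers; anything else maps to OTHER
GENE_LABELS <- c("LOR1", "LOR2", "LOR2B", "LOR3", "LOR3B", "OTHER")

#' Run an expression under a private RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator calls never disturb
#' the caller's random stream. Used by every stochastic operation that takes
#' a `seed` argument.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
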