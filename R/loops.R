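#' Configuration of the x(y)n Gly-loop grammar
#'
#' A Gly-loop is a glycine/serine-rich stretch `(y)_n` anchored ("indexed") on
#' an aromatic or aliphatic residue `x`, written `x(y)_n` with `n` the loop
#' size. This object fixes the grammar's residue sets and filters:
#'
#' * `index_residues` — the anchors `x`: aromatic \{F,Y,W\} plus aliphatic
#'   \{A,V,L,I,M\}. Aliphatic anchors commonly occur as dimers/trimers
#'   (II, MM, III); a maximal run collapses to a single boundary.
#' * `loop_alphabet` — residues allowed inside a loop, default \{G,S,C,K\}:
#'   the polar G/S body plus the conserved cysteines and lysines found at
#'   loop apices. Glutamine, proline and histidine act as spacers and
#'   terminate loops.
#' * `min_loop_len` — smallest reportable loop (default 2; the shortest loops
#'   observed in avian loricrins contain two residues).
#' * `min_gs_fraction` — minimum G+S share inside a loop for it to count as
#'   "gly-ser-rich" (default 0.6).
#' * `exclude_loops_with_X` — drop loops containing unknown residues
#'   (default `TRUE`), as required when counting NNN-free repeat units.
#'
#' @param index_residues Character vector of anchor residues.
#' @param loop_alphabet Character vector of loop residues.
#' @param min_loop_len Integer >= 1.
#' @param min_gs_fraction Fraction in \[0,1\].
#' @param exclude_loops_with_X Logical.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(index_residues = c("F", "Y", "W",
                                           "A", "V", "L", "I", "M"),
                        loop_alphabet = c("G", "S", "C", "K"),
                        min_loop_len = 2L,
                        min_gs_fraction = 0.6,
                        exclude_loops_with_X = TRUE) {
  index_residues <- toupper(index_residues)
  loop_alphabet <- toupper(loop_alphabet)
  if (length(intersect(index_residues, loop_alphabet))) {
    stop("index_residues and loop_alphabet must be disjoint", call. = FALSE)
  }
  if (any(c("P", "Q") %in% index_residues)) {
    stop("P and Q are spacer residues and cannot index loops", call. = FALSE)
  }
  stopifnot(min_loop_len >= 1L,
            min_gs_fraction >= 0, min_gs_fraction <= 1)
  structure(
    list(index_residues = index_residues,
         loop_alphabet = loop_alphabet,
         min_loop_len = as.integer(min_loop_len),
         min_gs_fraction = min_gs_fraction,
         exclude_loops_with_X = isTRUE(exclude_loops_with_X)),
    class = "loop_config"
  )
}

#' Detect Gly-loops in a residue segment
#'
#' Left-to-right scan implementing the x(y)n grammar: a maximal run of index
#' residues opens a candidate loop immediately to its right; the loop extends
#' through consecutive loop-alphabet residues and closes at the first residue
#' outside the alphabet (recording whether that closer is another index
#' residue, a terminator such as Q/P/H, or the sequence end). A candidate is
#' reported iff its size reaches `min_loop_len`, its G+S fraction reaches
#' `min_gs_fraction`, and (under `exclude_loops_with_X`) it contains no `X`.
#' Reported loops are non-overlapping and ordered by start.
#'
#' Coordinates are 0-based half-open: a loop spans residues
#' `[start, end)` and `size = end - start` is the `n` of `x(y)_n`.
#'
#' @param segment Residue string (X allowed); typically the central repeat
#'   domain of a loricrin.
#' @param config A [loop_config()].
#' @return A data frame with one row per loop: `start`, `end`, `size`,
#'   `left_index_pos` (0-based position of the rightmost residue of the
#'   anchoring index run), `x_residue`, `right_boundary_kind`
#'   (`"index"`, `"terminator"` or `"sequence_end"`), `gs_fraction`.
#' @examples
#' detect_gly_loops("YSGGGGYSGGGGCGGGSSGGGGGGGI")$size  # 5 18
#' @export
detect_gly_loops <- function(segment, config = loop_config()) {
  stopifnot(is.character(segment), length(segment) == 1L)
  empty <- data.frame(start = integer(0), end = integer(0), size = integer(0),
                      left_index_pos = integer(0), x_residue = character(0),
                      right_boundary_kind = character(0),
                      gs_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  L <- nchar(segment)
  if (L == 0L) return(empty)
  ch <- seq_chars(toupper(segment))
  is_index <- ch %in% config$index_residues
  # X (unknown) extends a loop body — it may stand for any residue — but
  # exclude_loops_with_X decides whether such a loop is reported
  is_loop <- ch %in% c(config$loop_alphabet, "X")

  out <- list()
  i <- 1L
  while (i <= L) {
    if (!is_index[i]) { i <- i + 1L; next }
    # maximal index run [i, j]
    j <- i
    while (j < L && is_index[j + 1L]) j <- j + 1L
    # candidate loop immediately right of the run
    k <- j + 1L
    while (k <= L && is_loop[k]) k <- k + 1L
    size <- k - j - 1L
    if (size >= config$min_loop_len) {
      body <- ch[(j + 1L):(k - 1L)]
      gs <- sum(body %in% c("G", "S")) / size
      has_x <- any(body == "X")
      if (gs >= config$min_gs_fraction &&
          !(config$exclude_loops_with_X && has_x)) {
        kind <- if (k > L) "sequence_end"
                else if (is_index[k]) "index"
                else "terminator"
        out[[length(out) + 1L]] <- data.frame(
          start = j, end = k - 1L, size = size,  # 0-based half-open
          left_index_pos = j - 1L, x_residue = ch[j],
          right_boundary_kind = kind, gs_fraction = gs,
          stringsAsFactors = FALSE
        )
      }
    }
    # resume at the closing residue (it may itself start an index run)
    i <- max(k, j + 1L)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Summarise detected loops into a Table-2-style profile
#'
#' @param loops Data frame from [detect_gly_loops()].
#' @return A one-row data frame: `total_loops`, `largest`, `smallest`,
#'   `mean_size` (arithmetic mean rounded to 2 dp). With no loops, the
#'   extrema and mean are `NA`.
#' @examples
#' loop_profile(detect_gly_loops("YSGGGGYSGGGGCGGGSSGGGGGGGI"))
#' @export
loop_profile <- function(loops) {
  if (is.null(loops) || nrow(loops) == 0L) {
    return(data.frame(total_loops = 0L, largest = NA_integer_,
                      smallest = NA_integer_, mean_size = NA_real_))
  }
  data.frame(total_loops = nrow(loops),
             largest = max(loops$size),
             smallest = min(loops$size),
             mean_size = round(mean(loops$size), 2))
}

#' Render the x(y)n annotation of one loop
#'
#' @param loop One row of a [detect_gly_loops()] data frame.
#' @param segment The residue string the loop was detected in.
#' @return A string such as `"Y(y)_5"`.
#' @export
xy_annotation <- function(loop, segment) {
  stopifnot(nrow(loop) == 1L)
  if (loop$start < 0L || loop$end > nchar(segment) ||
      loop$left_index_pos < 0L) {
    stop("loop out of range for segment", call. = FALSE)
  }
  x <- substring(segment, loop$left_index_pos + 1L, loop$left_index_pos + 1L)
  if (x != loop$x_residue) stop("loop does not match segment", call. = FALSE)
  sprintf("%s(y)_%d", x, loop$size)
}
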