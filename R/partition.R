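#' Construct a domain partition
#'
#' A half-open tiling of a protein into N-terminal `[0, a)`, central repeat
#' `[a, b)` and C-terminal `[b, L)` spans (0-based residue coordinates). The
#' central span may be empty.
#'
#' @param a,b,L Boundaries with `0 <= a <= b <= L`.
#' @return An object of class `domain_partition` with elements `n_term`,
#'   `central`, `c_term` (each a length-2 integer vector `c(from, to)`).
#' @export
domain_partition <- function(a, b, L) {
  a <- as.integer(a); b <- as.integer(b); L <- as.integer(L)
  if (!(0L <= a && a <= b && b <= L)) {
    stop("invalid partition: need 0 <= a <= b <= L", call. = FALSE)
  }
  structure(list(n_term = c(0L, a), central = c(a, b), c_term = c(b, L),
                 length = L),
            class = "domain_partition")
}

#' Partition a loricrin into N-terminal / central repeat / C-terminal domains
#'
#' Loricrins consist of conserved N- and C-terminal domains flanking a highly
#' variable glycine-rich repeat domain. In explicit mode the caller supplies
#' the three spans (e.g. from curation or an alignment to a reference). In
#' auto mode the central span is found heuristically: every window of
#' `window` residues whose combined G+S+X fraction reaches `gs_threshold`
#' marks the residues it covers, and the longest contiguous marked run
#' becomes the central domain. When reproducing published per-gene loop
#' counts, explicit spans should be supplied — the heuristic is only a
#' reasonable default.
#'
#' @param record A [protein_record()].
#' @param spans Optional list with `n_term`, `central`, `c_term` spans
#'   (each `c(from, to)`, 0-based half-open) that must tile the sequence.
#' @param window Auto mode: sliding window width in residues.
#' @param gs_threshold Auto mode: minimum G+S+X fraction within a window.
#' @param bridge Auto mode: covered runs separated by a gap shorter than
#'   this are merged. Default `2 * window`: the conserved termini that
#'   genuinely separate domains are themselves tens of residues long, so a
#'   shorter break inside a repeat region (a spacer/index cluster around a
#'   small loop) does not end the domain.
#' @return A [domain_partition()].
#' @export
partition_domains <- function(record, spans = NULL,
                              window = 10L, gs_threshold = 0.5,
                              bridge = 2L * window) {
  stopifnot(inherits(record, "protein_record"))
  L <- nchar(record$residues)
  if (!is.null(spans)) {
    a <- spans$central[1]; b <- spans$central[2]
    p <- domain_partition(a, b, L)
    if (!identical(as.integer(spans$n_term), p$n_term) ||
        !identical(as.integer(spans$c_term), p$c_term)) {
      stop("explicit spans do not tile the sequence", call. = FALSE)
    }
    return(p)
  }
  ch <- seq_chars(record$residues)
  gsx <- as.integer(ch %in% c("G", "S", "X"))
  if (L < window) return(domain_partition(0L, 0L, L))
  # window sums via cumulative sums; window i covers residues i .. i+window-1
  cs <- c(0L, cumsum(gsx))
  wsum <- cs[(window + 1L):(L + 1L)] - cs[1:(L - window + 1L)]
  pass <- wsum / window >= gs_threshold
  covered <- logical(L)
  for (i in which(pass)) covered[i:(i + window - 1L)] <- TRUE
  if (!any(covered)) return(domain_partition(0L, 0L, L))
  # close sub-terminus gaps between covered runs (see `bridge`)
  r <- rle(covered)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    r$values[inner][!r$values[inner] & r$lengths[inner] < bridge] <- TRUE
    covered <- inverse.rle(r)
    r <- rle(covered)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  domain_partition(starts[best] - 1L, ends[best], L)
}

# extract the residues of one span of a partition
span_residues <- function(record, span) {
  if (span[2] <= span[1]) return("")
  substring(record$residues, span[1] + 1L, span[2])
}
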