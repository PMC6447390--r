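#' Construct an aligned group of nucleotide sequences
#'
#' Equal-length, gapped nucleotide rows (alphabet `A,C,G,T,N,-`) holding a
#' multiple alignment of paralogs, the input to the gene-conversion fragment
#' scan.
#'
#' @param ids Character vector of row identifiers (>= 2, unique).
#' @param rows Character vector of aligned sequences, all the same length.
#' @return An object of class `aligned_group`.
#' @export
aligned_group <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(ids) >= 2L,
            !anyDuplicated(ids))
  rows <- toupper(rows)
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("rows must have equal length", call. = FALSE)
  for (i in seq_along(rows)) {
    check_alphabet(rows[i], c(NT_ALPHABET_N, "-"),
                   what = paste0("alignment row '", ids[i], "'"))
  }
  structure(list(ids = as.character(ids), rows = rows, length = len),
            class = "aligned_group")
}

#' Read an aligned FASTA into an aligned group
#'
#' @param path Aligned (gapped) nucleotide FASTA.
#' @return An [aligned_group()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "|", fixed = TRUE), `[[`,
                character(1), 1L)
  aligned_group(trimws(ids), as.character(set))
}

#' Polymorphic alignment columns
#'
#' Columns where at least two distinct bases occur among the rows. Columns
#' containing `N` or a gap in any row are excluded entirely (the scan
#' requires NNN-free input).
#'
#' @param group An [aligned_group()].
#' @return Integer vector of 0-based column indices, ascending.
#' @export
polymorphic_columns <- function(group) {
  m <- do.call(rbind, strsplit(group$rows, "", fixed = TRUE))
  usable <- colSums(m == "N" | m == "-") == 0L
  poly <- vapply(seq_len(ncol(m)), function(j) {
    usable[j] && length(unique(m[, j])) >= 2L
  }, logical(1))
  which(poly) - 1L
}

# maximal-sum contiguous segment of a score vector (Kadane). Ties go to the
# shortest segment, then the leftmost: resetting on a nonpositive running
# sum drops zero-sum prefixes, and the strict improvement test stops before
# zero-sum suffixes, so the reported fragment carries no uninformative flank
max_segment <- function(s) {
  best <- -Inf; bi <- bj <- 0L
  cur <- 0; ci <- 1L
  for (t in seq_along(s)) {
    if (cur <= 0) { cur <- 0; ci <- t }
    cur <- cur + s[t]
    # resetting on nonpositive running sums makes [ci, t] the shortest
    # max-sum segment ending at t; the tie-aware update then selects the
    # globally shortest (then leftmost) maximal segment
    better <- cur > best ||
      (cur == best && (t - ci < bj - bi ||
                         (t - ci == bj - bi && ci < bi)))
    if (better) { best <- cur; bi <- ci; bj <- t }
  }
  list(score = best, from = bi, to = bj)
}

# vectorised best-segment score only (used in the permutation loop)
max_segment_score <- function(s) {
  S <- cumsum(s)
  max(S - cummin(c(0, S[-length(S)])))
}

# score vector for one pair over the polymorphic columns
pair_scores <- function(m, i, j, poly0, mismatch_penalty) {
  agree <- m[i, poly0 + 1L] == m[j, poly0 + 1L]
  ifelse(agree, 1, -resolve_penalty(mismatch_penalty, agree))
}

# "auto" scales the penalty to the pair's background agreement rate a so the
# expected per-site drift a - (1-a)*g is negative (g = 2a/(1-a), floored at
# 1): with a fixed penalty a pair agreeing at more than g/(g+1) of the
# polymorphic sites has positive drift and the maximal segment degenerates
# to (nearly) the whole sequence, destroying localization
resolve_penalty <- function(mismatch_penalty, agree) {
  if (identical(mismatch_penalty, "auto")) {
    a <- mean(agree)
    max(1, min(2 * a / max(1 - a, 1e-9), 1e6))
  } else {
    stopifnot(is.numeric(mismatch_penalty), mismatch_penalty > 0)
    mismatch_penalty
  }
}

#' Best-scoring homogenized fragment between two aligned paralogs
#'
#' Over the sequence of polymorphic columns, the pair scores +1 where it
#' agrees and `-mismatch_penalty` where it differs; the candidate
#' gene-conversion ("global") fragment is the maximal-sum contiguous segment,
#' found by a linear scan. Coordinates span the first to last polymorphic
#' column of the segment, in 0-based half-open alignment coordinates.
#'
#' @param group An [aligned_group()].
#' @param pair Character vector of two row ids.
#' @param mismatch_penalty Positive penalty per disagreeing site (default 2).
#' @return A one-row data frame (`id1`, `id2`, `start`, `end`, `nt_length`,
#'   `n_poly_sites`, `score`), or `NULL` when the group has no polymorphic
#'   columns.
#' @export
pair_fragment_scan <- function(group, pair, mismatch_penalty = 2.0) {
  stopifnot(inherits(group, "aligned_group"), length(pair) == 2L,
            all(pair %in% group$ids))
  poly0 <- polymorphic_columns(group)
  if (length(poly0) == 0L) return(NULL)
  m <- do.call(rbind, strsplit(group$rows, "", fixed = TRUE))
  i <- match(pair[1], group$ids); j <- match(pair[2], group$ids)
  s <- pair_scores(m, i, j, poly0, mismatch_penalty)
  seg <- max_segment(s)
  start <- poly0[seg$from]
  end <- poly0[seg$to] + 1L
  data.frame(id1 = pair[1], id2 = pair[2],
             start = start, end = end, nt_length = end - start,
             n_poly_sites = seg$to - seg$from + 1L,
             score = seg$score,
             stringsAsFactors = FALSE)
}

#' Permutation test for gene-conversion fragments across all pairs
#'
#' For every pair of rows the observed best-fragment score is compared with a
#' null distribution obtained by jointly permuting the order of the
#' polymorphic columns (the same permutation for all rows), rescanning every
#' pair, and recording the per-permutation maximum score over all pairs.
#' Using the all-pairs maximum in the null gives family-wise control over
#' the multiple pairs, analogous to a single corrected p-value per group.
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)` and is
#' deterministic given `seed`.
#'
#' @param group An [aligned_group()].
#' @param n_permutations Number of permutations (default 10000; below 100 a
#'   warning is logged).
#' @param seed Integer seed driving a private random stream.
#' @param mismatch_penalty Numeric penalty, or `"auto"` (default) which
#'   scales the penalty to each pair's background agreement rate `a` as
#'   `max(1, 2a/(1-a))` so the expected per-site score stays negative and
#'   the maximal segment localizes; the scaling is a function of the score
#'   multiset and hence identical across permutations, so exchangeability
#'   (and calibration) is preserved.
#' @param pairs Optional list of id pairs to scan; default every pair of
#'   rows. Note that with exactly two rows in the group the statistic is
#'   degenerate (the pair disagrees at every polymorphic column by
#'   definition); meaningful scans need further rows — outgroup sequences —
#'   to define the polymorphic sites, as in the original multi-species
#'   analyses.
#' @return Data frame with one row per pair: fragment columns from
#'   [pair_fragment_scan()] plus `p_value`; `NULL` when there are no
#'   polymorphic columns.
#' @export
permutation_test <- function(group, n_permutations = 10000L, seed,
                             mismatch_penalty = "auto", pairs = NULL) {
  stopifnot(inherits(group, "aligned_group"))
  if (n_permutations < 100L) {
    warning("n_permutations < 100: p-values will be very coarse")
  }
  poly0 <- polymorphic_columns(group)
  if (length(poly0) == 0L) return(NULL)
  m <- do.call(rbind, strsplit(group$rows, "", fixed = TRUE))
  if (is.null(pairs)) pairs <- utils::combn(group$ids, 2L, simplify = FALSE)
  score_vecs <- lapply(pairs, function(p) {
    pair_scores(m, match(p[1], group$ids), match(p[2], group$ids),
                poly0, mismatch_penalty)
  })
  frags <- do.call(rbind, lapply(pairs, function(p) {
    pair_fragment_scan(group, p, mismatch_penalty)
  }))
  npoly <- length(poly0)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- sample.int(npoly)
      max(vapply(score_vecs, function(s) max_segment_score(s[perm]),
                 numeric(1)))
    }, numeric(1))
  })
  # observed scores recomputed along the same arithmetic route as the null
  # so that exact ties compare exactly
  obs <- vapply(score_vecs, max_segment_score, numeric(1))
  frags$p_value <- vapply(obs, function(o) {
    (1 + sum(null_max >= o)) / (1 + n_permutations)
  }, numeric(1))
  frags
}
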