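# Independent oracles used to freeze expected values. These deliberately use
# different computational routes than the package implementations.

# Brute-force Gly-loop enumerator: list every maximal index run, pair it with
# the maximal loop-alphabet run starting immediately to its right, then apply
# the filters. Independent of the left-to-right scanning implementation.
oracle_loops <- function(segment, config = loop_config()) {
  ch <- strsplit(toupper(segment), "")[[1]]
  L <- length(ch)
  empty <- data.frame(start = integer(0), end = integer(0), size = integer(0),
                      x_residue = character(0),
                      right_boundary_kind = character(0),
                      gs_fraction = numeric(0), stringsAsFactors = FALSE)
  if (L == 0L) return(empty)
  is_idx <- ch %in% config$index_residues
  is_loop <- ch %in% c(config$loop_alphabet, "X")
  r <- rle(is_idx)
  run_end <- cumsum(r$lengths)
  out <- list()
  for (k in which(r$values)) {
    j <- run_end[k]                      # 1-based last residue of index run
    if (j + 1L > L || !is_loop[j + 1L]) next
    m <- j + 1L
    while (m < L && is_loop[m + 1L]) m <- m + 1L
    size <- m - j
    body <- ch[(j + 1L):m]
    gs <- mean(body %in% c("G", "S"))
    ok <- size >= config$min_loop_len && gs >= config$min_gs_fraction &&
      !(config$exclude_loops_with_X && any(body == "X"))
    if (!ok) next
    kind <- if (m == L) "sequence_end" else if (is_idx[m + 1L]) "index"
            else "terminator"
    out[[length(out) + 1L]] <- data.frame(
      start = j, end = m, size = size, x_residue = ch[j],
      right_boundary_kind = kind, gs_fraction = gs,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Exhaustive maximal-segment enumeration (all O(m^2) segments); ties broken
# by shortest segment then smallest start, matching the documented
# convention.
oracle_best_segment <- function(s) {
  best <- list(score = -Inf, from = 0L, to = 0L)
  for (i in seq_along(s)) {
    acc <- 0
    for (j in i:length(s)) {
      acc <- acc + s[j]
      better <- acc > best$score ||
        (acc == best$score &&
           (j - i < best$to - best$from ||
              (j - i == best$to - best$from && i < best$from)))
      if (better) best <- list(score = acc, from = i, to = j)
    }
  }
  best
}

# Textbook sum-of-squares one-way ANOVA.
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- length(all) - length(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# Closed-form Welch statistic and Welch-Satterthwaite df.
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Variance proportions from the eigendecomposition of the covariance matrix.
oracle_pca_proportions <- function(m) {
  ev <- eigen(stats::cov(m), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}

# All strings of a given length over an alphabet.
all_strings <- function(len, alphabet) {
  if (len == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len), stringsAsFactors = FALSE))
  do.call(paste0, grid)
}
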