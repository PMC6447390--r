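#' Amino-acid composition of a protein record
#'
#' Percent composition over the 20 standard residues, computed over known
#' residues only — unknown residues (`X`, from NNN assembly gaps) are
#' excluded from the denominator so that percentages stay comparable across
#' degradation levels. Records whose unknown fraction exceeds
#' `max_unknown_fraction` are rejected, mirroring the "<10% NNNs" filter
#' applied before composition analyses.
#'
#' @param record A [protein_record()].
#' @param max_unknown_fraction Maximum tolerated X fraction (default 0.10).
#' @return A list of class `composition_vector`: `percents` (named numeric,
#'   length 20, sums to 100), `n_known`, `n_unknown`.
#' @examples
#' composition_vector(protein_record("a", "GGSS"))$percents[c("G", "S")]
#' @export
composition_vector <- function(record, max_unknown_fraction = 0.10) {
  stopifnot(inherits(record, "protein_record"))
  ch <- seq_chars(record$residues)
  n_unknown <- sum(ch == "X")
  n_known <- length(ch) - n_unknown
  frac <- n_unknown / length(ch)
  if (n_known == 0L || frac > max_unknown_fraction) {
    stop(sprintf(
      "record '%s' rejected: unknown fraction %.3f exceeds threshold %.3f",
      record$id, frac, max_unknown_fraction), call. = FALSE)
  }
  counts <- table(factor(ch[ch != "X"], levels = AA_STANDARD))
  percents <- 100 * as.numeric(counts) / n_known
  names(percents) <- AA_STANDARD
  structure(list(percents = percents, n_known = n_known,
                 n_unknown = n_unknown),
            class = "composition_vector")
}

#' Composition matrix for a set of records
#'
#' @param records List of [protein_record()]s.
#' @param max_unknown_fraction Passed to [composition_vector()].
#' @return Numeric matrix, samples x 20 residues, rownames = record ids.
#' @export
composition_matrix <- function(records, max_unknown_fraction = 0.10) {
  rows <- lapply(records, composition_vector,
                 max_unknown_fraction = max_unknown_fraction)
  m <- do.call(rbind, lapply(rows, `[[`, "percents"))
  rownames(m) <- vapply(records, `[[`, character(1), "id")
  m
}

#' One-way fixed-effects ANOVA on a single residue's percentages
#'
#' Compares the mean percent content of one residue across groups of
#' composition vectors (e.g. the LOR1 vs LOR3 gene families) by classical
#' one-way ANOVA.
#'
#' @param groups Named list; each element a list of `composition_vector`s or
#'   a numeric vector of percentages for the chosen residue.
#' @param residue One of the 20 standard residues (ignored when `groups`
#'   already holds numeric vectors).
#' @return A list of class `stat_result`: `statistic` (F), `df`
#'   (between, within), `p_value`, `group_means`, `group_sizes`.
#' @export
residue_anova <- function(groups, residue = NULL) {
  vals <- lapply(groups, function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    stopifnot(!is.null(residue), residue %in% AA_STANDARD)
    vapply(g, function(v) v$percents[[residue]], numeric(1))
  })
  if (length(vals) < 2L || any(lengths(vals) < 2L)) {
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  }
  y <- unlist(vals, use.names = FALSE)
  f <- factor(rep(seq_along(vals), lengths(vals)))
  fit <- stats::anova(stats::lm(y ~ f))
  Fstat <- fit[["F value"]][1]
  p <- fit[["Pr(>F)"]][1]
  if (is.na(Fstat)) { Fstat <- 0; p <- 1 }  # zero variance everywhere
  structure(list(statistic = Fstat,
                 df = c(between = fit$Df[1], within = fit$Df[2]),
                 p_value = p,
                 group_means = vapply(vals, mean, numeric(1)),
                 group_sizes = lengths(vals)),
            class = "stat_result")
}

#' Welch's two-sample t-test on percentage vectors
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. The degenerate case of two zero-variance samples
#' with equal means returns `t = 0, p = 1` rather than an error.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return A `stat_result` list: `statistic` (t), `df`, `p_value`,
#'   `group_means`, `group_sizes`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(statistic = 0, df = c(df = NA_real_),
                            p_value = 1,
                            group_means = c(mean(a), mean(b)),
                            group_sizes = c(length(a), length(b))),
                       class = "stat_result"))
    }
    stop("both samples have zero variance with different means",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 df = c(df = unname(tt$parameter)),
                 p_value = tt$p.value,
                 group_means = c(mean(a), mean(b)),
                 group_sizes = c(length(a), length(b))),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> statistic = %.4g, df = (%s), p = %.4g\n",
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' PCA of composition vectors via singular-value decomposition
#'
#' Column-centres (and optionally unit-scales) the samples-by-residues
#' percentage matrix and decomposes it by SVD. Scores are `U %*% S`,
#' loadings the right singular vectors, and the per-component variance
#' proportions are the squared singular values normalised to sum to one.
#' The default is centre-only (no unit-variance scaling), matching the SVD
#' default of the common PCA implementations for composition data.
#'
#' @param m Numeric matrix, samples x residues; >= 2 rows, no missing values.
#' @param center,scale Logical; column centring / unit scaling.
#' @return A list of class `pca_result`: `scores`, `loadings`,
#'   `variance_proportions`, `sdev`.
#' @export
pca_svd <- function(m, center = TRUE, scale = FALSE) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2L, !anyNA(m))
  sds <- apply(m, 2, stats::sd)
  if (all(sds == 0)) stop("constant matrix: variance proportions undefined",
                          call. = FALSE)
  if (scale && any(sds == 0)) {
    # drop constant columns before unit scaling, as prcomp would refuse them
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = center, scale. = scale)
  v <- pc$sdev^2
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 variance_proportions = v / sum(v),
                 sdev = pc$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$variance_proportions))
  cat("<pca_result>", nrow(x$scores), "samples;",
      "top variance proportions:",
      paste(sprintf("%.4f", x$variance_proportions[1:k]), collapse = " "),
      "\n")
  invisible(x)
}
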