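#' Parameters for the loricrin-like sequence generator
#'
#' The generator emulates the tripartite loricrin architecture: conserved
#' N- and C-terminal domains (lysine/glutamine-rich, low in G/S) flanking a
#' central quasi-repeat domain built from alternating blocks of an index-run
#' (the anchoring `x` residues), a glycine/serine-rich loop body, and a
#' glutamine/proline-style spacer that terminates the loop.
#'
#' Index styles mirror the three avian gene families:
#' * `LOR1_like` — isoleucine-indexed (I/II) with `HQSQGP`-style spacers;
#' * `LOR2_like` — methionine-indexed (M/MM);
#' * `LOR3_like` — tyrosine- or isoleucine-indexed (Y/II/III), loops
#'   containing occasional C and K.
#'
#' Defaults state a chicken-LOR3-like gene: 43 loops with sizes uniform on
#' 3..26 (the published range for that gene), bodies drawn mostly from G and
#' S with C/K admixture, and every loop constrained to a G+S fraction of at
#' least 0.6 so planted loops are recoverable exactly by the detector.
#'
#' @param n_loops Number of loops to plant (>= 0).
#' @param loop_size_sampler Either `list(min =, max =)` for uniform sampling
#'   or an integer vector of sizes to sample from (all >= 2).
#' @param index_style `"LOR1_like"`, `"LOR2_like"` or `"LOR3_like"`.
#' @param terminus_templates Character vector of two residue strings (N- and
#'   C-terminal domains); must not contain index or loop-alphabet G/S runs.
#' @param loop_alphabet_weights Named nonnegative weights over G,S,C,K.
#' @param seed Integer seed.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_loops = 43L,
                             loop_size_sampler = list(min = 3L, max = 26L),
                             index_style = c("LOR3_like", "LOR1_like",
                                             "LOR2_like"),
                             terminus_templates = c("MQSKKQPEPQPPTDHQK",
                                                    "QPKCPEPQTQKKPHHQ"),
                             loop_alphabet_weights = c(G = 0.55, S = 0.30,
                                                       C = 0.10, K = 0.05),
                             seed = 1L) {
  index_style <- match.arg(index_style)
  stopifnot(n_loops >= 0L, length(terminus_templates) == 2L)
  w <- loop_alphabet_weights[c("G", "S", "C", "K")]
  if (anyNA(w) || any(w < 0) || sum(w) == 0) {
    stop("loop_alphabet_weights must be nonnegative over G,S,C,K, not all 0",
         call. = FALSE)
  }
  if (is.list(loop_size_sampler)) {
    stopifnot(loop_size_sampler$min >= 2L,
              loop_size_sampler$max >= loop_size_sampler$min)
  } else {
    stopifnot(all(loop_size_sampler >= 2L))
  }
  structure(list(n_loops = as.integer(n_loops),
                 loop_size_sampler = loop_size_sampler,
                 index_style = index_style,
                 terminus_templates = toupper(terminus_templates),
                 loop_alphabet_weights = w,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# style-specific building blocks
style_blocks <- function(style) {
  switch(style,
         LOR1_like = list(index = c("I", "II"), spacer = c("HQSQGP", "QP")),
         LOR2_like = list(index = c("M", "MM"), spacer = c("QP", "HQ")),
         LOR3_like = list(index = c("Y", "II", "III"),
                          spacer = c("QH", "QP")))
}

sample_sizes <- function(sampler, n) {
  if (n == 0L) return(integer(0))
  if (is.list(sampler)) {
    sample(sampler$min:sampler$max, n, replace = TRUE)
  } else {
    sample(as.integer(sampler), n, replace = TRUE)
  }
}

# draw one loop body of the given size with G+S fraction >= min_gs
sample_loop_body <- function(size, weights, min_gs = 0.6) {
  res <- sample(names(weights), size, replace = TRUE, prob = weights)
  need <- ceiling(min_gs * size)
  while (sum(res %in% c("G", "S")) < need) {
    k <- which(!(res %in% c("G", "S")))[1]
    res[k] <- sample(c("G", "S"), 1L,
                     prob = weights[c("G", "S")] + 1e-9)
  }
  paste(res, collapse = "")
}

#' Generate one loricrin-like protein with ground truth
#'
#' Builds `N-terminus + (index-run, loop, spacer) blocks + C-terminus` and
#' records every planted loop (0-based half-open coordinates matching what
#' [detect_gly_loops()] reports) and the central span. Deterministic given
#' `params$seed`.
#'
#' @param params A [generator_params()].
#' @param id,species_code,gene_label Metadata for the resulting record.
#' @return A list with `record` (a [protein_record()]) and `truth` (class
#'   `synthetic_truth`: `planted_loops` data frame with `start`, `end`,
#'   `size`; `central_span`; `params`; `seed`).
#' @export
generate_loricrin_protein <- function(params = generator_params(),
                                      id = "synthetic1",
                                      species_code = "SYNTH",
                                      gene_label = "OTHER") {
  stopifnot(inherits(params, "generator_params"))
  blocks <- style_blocks(params$index_style)
  out <- with_seed(params$seed, {
    sizes <- sample_sizes(params$loop_size_sampler, params$n_loops)
    n_term <- params$terminus_templates[1]
    pieces <- character(0)
    loops <- list()
    pos <- nchar(n_term)  # 0-based cursor
    central_start <- pos
    for (k in seq_len(params$n_loops)) {
      idx <- sample(blocks$index, 1L)
      body <- sample_loop_body(sizes[k], params$loop_alphabet_weights)
      spc <- sample(blocks$spacer, 1L)
      start <- pos + nchar(idx)
      loops[[k]] <- data.frame(start = start, end = start + sizes[k],
                               size = sizes[k])
      pieces <- c(pieces, idx, body, spc)
      pos <- pos + nchar(idx) + sizes[k] + nchar(spc)
    }
    central_end <- pos
    seqstr <- paste0(n_term, paste(pieces, collapse = ""),
                     params$terminus_templates[2])
    list(seqstr = seqstr,
         loops = if (length(loops)) do.call(rbind, loops)
                 else data.frame(start = integer(0), end = integer(0),
                                 size = integer(0)),
         central = c(central_start, central_end))
  })
  record <- protein_record(id, out$seqstr, species_code = species_code,
                           gene_label = gene_label)
  truth <- structure(list(planted_loops = out$loops,
                          central_span = out$central,
                          planted_tract = NULL,
                          params = params, seed = params$seed),
                     class = "synthetic_truth")
  list(record = record, truth = truth)
}

#' Degrade a record with unknown residues (X)
#'
#' Emulates assembly-gap NNN runs: residues in the chosen placement region
#' are replaced by `X` in contiguous runs until the region's X fraction is
#' within `1/region_length` of `target_fraction`. Placements:
#' `"anywhere"` (whole sequence), `"central_only"` (the truth's central
#' span), `"spacers_only"` (central residues outside planted loops and index
#' runs, so the loop profile is provably unaffected).
#'
#' @param record A [protein_record()].
#' @param target_fraction Target X fraction in `[0, 1)`.
#' @param placement One of `"central_only"`, `"anywhere"`, `"spacers_only"`.
#' @param seed Integer seed.
#' @param truth The `synthetic_truth` of the record; required for the
#'   central/spacer placements.
#' @return The degraded [protein_record()].
#' @export
degrade_with_unknowns <- function(record, target_fraction,
                                  placement = c("central_only", "anywhere",
                                                "spacers_only"),
                                  seed = 1L, truth = NULL) {
  placement <- match.arg(placement)
  stopifnot(target_fraction >= 0, target_fraction < 1)
  ch <- seq_chars(record$residues)
  L <- length(ch)
  region <- switch(placement,
    anywhere = seq_len(L),
    central_only = {
      stopifnot(!is.null(truth))
      a <- truth$central_span[1]; b <- truth$central_span[2]
      if (b > a) (a + 1L):b else integer(0)
    },
    spacers_only = {
      stopifnot(!is.null(truth))
      a <- truth$central_span[1]; b <- truth$central_span[2]
      cand <- if (b > a) (a + 1L):b else integer(0)
      in_loop <- rep(FALSE, L)
      if (nrow(truth$planted_loops)) {
        for (r in seq_len(nrow(truth$planted_loops))) {
          lo <- truth$planted_loops$start[r]; hi <- truth$planted_loops$end[r]
          # protect the first spacer residue after the loop as well: an X
          # there would extend the loop body (X may stand for any residue)
          # and disqualify it under exclude_loops_with_X
          in_loop[(lo + 1L):min(hi + 1L, L)] <- TRUE
        }
      }
      idx_set <- loop_config()$index_residues
      cand[!in_loop[cand] & !(ch[cand] %in% idx_set)]
    })
  n_region <- length(region)
  if (target_fraction > 0 && n_region == 0L) {
    stop("region too short: achievable fraction is 0.000", call. = FALSE)
  }
  target_n <- round(target_fraction * n_region)
  if (target_n == 0L) return(record)
  ch <- with_seed(seed, {
    placed <- sum(ch[region] == "X")
    guard <- 0L
    while (placed < target_n && guard < 10000L) {
      run <- sample(3:10, 1L)
      t0 <- sample.int(n_region, 1L)
      idx <- region[t0:min(n_region, t0 + run - 1L)]
      idx <- idx[ch[idx] != "X"]
      idx <- utils::head(idx, target_n - placed)
      ch[idx] <- "X"
      placed <- placed + length(idx)
      guard <- guard + 1L
    }
    if (placed < target_n) {  # deterministic fallback, never expected
      left <- region[ch[region] != "X"]
      ch[utils::head(left, target_n - placed)] <- "X"
    }
    ch
  })
  protein_record(record$id, paste(ch, collapse = ""),
                 species_code = record$species_code,
                 gene_label = record$gene_label,
                 source_note = record$source_note)
}

# codons per amino acid under the standard code (stops excluded)
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Generate a diverged duplicate gene pair with an optional conversion tract
#'
#' Generates a loricrin-like protein, back-translates it to a CDS with
#' uniform synonymous codon choice, duplicates it, applies independent
#' per-site substitutions (probability `divergence`, uniform over the three
#' alternative bases) to the second copy, and — if `tract` is given —
#' overwrites that window of the second copy with the first copy's bases,
#' emulating a homogenizing gene-conversion event between tandem duplicates.
#'
#' @param protein_params A [generator_params()] for the ancestral protein.
#' @param divergence Per-site substitution probability in `[0, 0.75)`.
#' @param tract Optional `c(start_fraction, length_columns)`: the converted
#'   window starts at `round(start_fraction * (L - length))`.
#' @param seed Integer seed for the nucleotide stage.
#' @param ids Row identifiers for the two copies.
#' @param n_outgroups Number of additional diverged rows appended after the
#'   pair. The fragment statistic defines polymorphic sites over the whole
#'   group, so a pair on its own is degenerate (it disagrees at every
#'   polymorphic column); outgroups play the role of the further species in
#'   a real paralog alignment.
#' @param outgroup_divergence Per-site substitution probability for each
#'   outgroup row relative to the ancestor.
#' @return A list with `group` (an [aligned_group()], gapless) and `truth`
#'   (`synthetic_truth` carrying `planted_tract` as a 0-based half-open
#'   column span, or `NULL`).
#' @export
generate_duplicate_pair <- function(protein_params = generator_params(),
                                    divergence = 0.2, tract = NULL,
                                    seed = 1L,
                                    ids = c("copyA", "copyB"),
                                    n_outgroups = 0L,
                                    outgroup_divergence = 0.3) {
  stopifnot(divergence >= 0, divergence < 0.75)
  prot <- generate_loricrin_protein(protein_params)
  codons <- aa_codon_table()
  out <- with_seed(seed, {
    aa <- seq_chars(prot$record$residues)
    cds1 <- paste(vapply(aa, function(a) {
      opts <- codons[[a]]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, character(1)), collapse = "")
    b1 <- seq_chars(cds1)
    L <- length(b1)
    b2 <- b1
    hit <- which(stats::runif(L) < divergence)
    if (length(hit)) {
      b2[hit] <- vapply(b1[hit], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1L)
      }, character(1))
    }
    span <- NULL
    if (!is.null(tract)) {
      tlen <- as.integer(tract[2])
      if (tlen > L) stop("tract longer than sequence", call. = FALSE)
      t0 <- round(tract[1] * (L - tlen))
      b2[(t0 + 1L):(t0 + tlen)] <- b1[(t0 + 1L):(t0 + tlen)]
      span <- c(t0, t0 + tlen)
    }
    rows <- c(paste(b1, collapse = ""), paste(b2, collapse = ""))
    for (o in seq_len(n_outgroups)) {
      bo <- b1
      hit <- which(stats::runif(L) < outgroup_divergence)
      if (length(hit)) {
        bo[hit] <- vapply(b1[hit], function(x) {
          sample(setdiff(c("A", "C", "G", "T"), x), 1L)
        }, character(1))
      }
      rows <- c(rows, paste(bo, collapse = ""))
    }
    list(rows = rows, span = span)
  })
  truth <- prot$truth
  truth$planted_tract <- out$span
  all_ids <- c(ids, if (n_outgroups > 0L) paste0("outgroup", seq_len(n_outgroups)))
  list(group = aligned_group(all_ids, out$rows), truth = truth)
}
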