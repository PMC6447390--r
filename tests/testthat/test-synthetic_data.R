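test_that("generation is deterministic given the seed", {
  p <- generator_params(n_loops = 12, seed = 77)
  a <- generate_loricrin_protein(p)
  b <- generate_loricrin_protein(p)
  expect_identical(a$record$residues, b$record$residues)
  expect_identical(a$truth$planted_loops, b$truth$planted_loops)
  c <- generate_loricrin_protein(generator_params(n_loops = 12, seed = 78))
  expect_false(identical(a$record$residues, c$record$residues))
})

test_that("planted loops are recovered exactly by the detector", {
  for (st in c("LOR1_like", "LOR2_like", "LOR3_like")) {
    g <- generate_loricrin_protein(
      generator_params(n_loops = 10,
                       loop_size_sampler = list(min = 4L, max = 8L),
                       index_style = st, seed = 15))
    central <- substring(g$record$residues, g$truth$central_span[1] + 1,
                         g$truth$central_span[2])
    loops <- detect_gly_loops(central)
    expect_equal(nrow(loops), 10L)
    expect_equal(loops$start + g$truth$central_span[1],
                 g$truth$planted_loops$start)
    expect_equal(loops$size, g$truth$planted_loops$size)
  }
  # zero loops -> empty central block, nothing detected
  g0 <- generate_loricrin_protein(generator_params(n_loops = 0, seed = 1))
  expect_equal(g0$truth$central_span[1], g0$truth$central_span[2])
  expect_equal(nrow(g0$truth$planted_loops), 0L)
})

test_that("planted profile extrema match the truth for a full-size gene", {
  g <- generate_loricrin_protein(generator_params(seed = 6))  # 43 loops, 3-26
  central <- substring(g$record$residues, g$truth$central_span[1] + 1,
                       g$truth$central_span[2])
  prof <- loop_profile(detect_gly_loops(central))
  expect_equal(prof$total_loops, 43L)
  expect_equal(prof$largest, max(g$truth$planted_loops$size))
  expect_equal(prof$smallest, min(g$truth$planted_loops$size))
  expect_equal(prof$mean_size, round(mean(g$truth$planted_loops$size), 2))
})

test_that("generator output satisfies the module invariants", {
  g <- generate_loricrin_protein(generator_params(n_loops = 25, seed = 44))
  tl <- g$truth$planted_loops
  expect_true(all(tl$start >= g$truth$central_span[1]))
  expect_true(all(tl$end <= g$truth$central_span[2]))
  expect_true(all(tl$start[-1] >= tl$end[-nrow(tl)]))  # ordered, disjoint
  expect_true(grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", g$record$residues))
})

test_that("spacer-only degradation leaves the loop profile unchanged", {
  g <- generate_loricrin_protein(generator_params(n_loops = 15, seed = 23))
  central_span <- g$truth$central_span
  clean <- loop_profile(detect_gly_loops(
    substring(g$record$residues, central_span[1] + 1, central_span[2])))
  deg <- degrade_with_unknowns(g$record, 0.10, "spacers_only", seed = 3,
                               truth = g$truth)
  degraded <- loop_profile(detect_gly_loops(
    substring(deg$residues, central_span[1] + 1, central_span[2])))
  expect_equal(degraded, clean)
})

test_that("degradation errors when the region cannot reach the target", {
  g <- generate_loricrin_protein(generator_params(n_loops = 0, seed = 2))
  expect_error(degrade_with_unknowns(g$record, 0.5, "central_only",
                                     seed = 1, truth = g$truth),
               "achievable")
})

test_that("duplicate pairs have the stated divergence and alignment shape", {
  diffs <- vapply(1:30, function(r) {
    gp <- generate_duplicate_pair(generator_params(n_loops = 8,
                                                   seed = 700 + r),
                                  divergence = 0.2, seed = 800 + r)
    b <- strsplit(gp$group$rows, "")
    mean(b[[1]] != b[[2]])
  }, numeric(1))
  # per-site substitution probability 0.2; binomial 3-SD band on the mean
  L <- 8 * 20 * 3  # rough per-gene nucleotide count, for the SD scale
  expect_lt(abs(mean(diffs) - 0.2), 3 * sqrt(0.2 * 0.8 / (30 * L)))

  gp0 <- generate_duplicate_pair(generator_params(n_loops = 5, seed = 3),
                                 divergence = 0, seed = 4)
  expect_identical(gp0$group$rows[1], gp0$group$rows[2])
  expect_equal(length(polymorphic_columns(gp0$group)), 0L)

  # planted tract coordinates are recorded and columns inside it identical
  gpt <- generate_duplicate_pair(generator_params(n_loops = 10, seed = 5),
                                 divergence = 0.3, tract = c(0.5, 90),
                                 seed = 6)
  tr <- gpt$truth$planted_tract
  expect_equal(tr[2] - tr[1], 90)
  b <- strsplit(gpt$group$rows, "")
  expect_true(all(b[[1]][(tr[1] + 1):tr[2]] == b[[2]][(tr[1] + 1):tr[2]]))
  expect_error(generate_duplicate_pair(
    generator_params(n_loops = 2, seed = 1), divergence = 0.1,
    tract = c(0, 1e6), seed = 1), "tract longer")
})

test_that("full pipeline smoke test runs end to end", {
  t0 <- Sys.time()
  recs <- lapply(1:50, function(s) {
    g <- generate_loricrin_protein(generator_params(n_loops = 10,
                                                    seed = 900 + s),
                                   id = paste0("r", s))
    rec <- if (s %% 2 == 0) {
      degrade_with_unknowns(g$record, 0.2, "central_only", seed = s,
                            truth = g$truth)
    } else {
      g$record
    }
    part <- partition_domains(rec)
    central <- substring(rec$residues, part$central[1] + 1, part$central[2])
    loops <- detect_gly_loops(central)
    qa <- assess_quality(rec, part, reference_length = nchar(rec$residues))
    list(rec = rec, profile = loop_profile(loops), qa = qa)
  })
  comp <- composition_matrix(Filter(
    function(r) r$qa$central_unknown_fraction <= 0.10,
    recs) |> lapply(function(r) r$rec))
  expect_gte(nrow(comp), 2L)
  pc <- pca_svd(comp)
  expect_true(all(diff(pc$variance_proportions) <= 1e-12))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
})
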