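test_that("lineage and library constructors validate their fields", {
  expect_error(lineage_spec("v1", "viral", relative_abundance = 1.2,
                            turnover_theta = 0.5), "relative_abundance")
  expect_error(lineage_spec("v1", "viral", relative_abundance = 1,
                            turnover_theta = 1.5), "turnover_theta")
  expect_error(lineage_spec("v1", "viral", relative_abundance = 1,
                            turnover_theta = 0.5, genome_length_bp = -5),
               "genome_length_bp")
  expect_error(sorted_library("x", "viral_progeny", sorted_depth = 0),
               "sorted_depth")
  # BONCAT state follows from the fraction
  expect_true(sorted_library("x", "viral_progeny", 10)$boncat_positive)
  expect_true(sorted_library("x", "active_cells", 10)$boncat_positive)
  expect_false(sorted_library("x", "pre_existing_viruses", 10)$boncat_positive)
  # abundances must sum to 1 within a kind
  v <- lineage_spec("v1", "viral", 0.6, turnover_theta = 0.5)
  w <- lineage_spec("v2", "viral", 0.6, turnover_theta = 0.5)
  lib <- list(sorted_library("pos", "viral_progeny", 10))
  expect_error(community_spec(list(v, w), lib), "sum to 1")
})

test_that("zero divergence yields identical proteins across variants", {
  spec <- small_spec(theta = c(1), seed = 3)
  spec$lineages[[1]]$protein_divergence <- 0
  lin <- generate_lineages(spec, seed = 3)[[1]]
  for (v in lin$variants) {
    expect_identical(unname(v), unname(lin$proteins))
  }
})

test_that("simulator is deterministic under a fixed seed, including files", {
  spec <- small_spec(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_community(spec, outdir = d1)
  s2 <- simulate_community(spec, outdir = d2)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$hits, s2$hits)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
  # tables are identical whether or not files are emitted
  s3 <- simulate_community(spec)
  expect_identical(s1$contigs, s3$contigs)
  expect_identical(s1$evidence, s3$evidence)
})

test_that("variant divergence matches its binomial expectation", {
  # 0.1 per-site divergence on 1000-aa proteins: identity 90% +/- 2%
  spec <- community_spec(
    list(lineage_spec("v1", "viral", 1, turnover_theta = 0.5,
                      n_proteins = 30L, protein_divergence = 0.1)),
    list(sorted_library("pos", "viral_progeny", 100)),
    n_variants = 4L, seed = 5
  )
  lin <- generate_lineages(spec, seed = 5)[[1]]
  ids <- function(x, y) {
    a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
    mean(a == b)
  }
  # measured on the generator's own variants vs the ancestral repertoire
  idents <- unlist(lapply(lin$variants, function(v) {
    mapply(ids, unname(v), unname(lin$proteins))
  }))
  expect_gt(mean(idents), 0.88)
  expect_lt(mean(idents), 0.92)
})

test_that("sorting conserves depth and splits progeny by abundance * theta", {
  spec <- small_spec(theta = c(0.8, 0.2), seed = 21)
  cnt <- simulate_sorting(spec, seed = 21)
  tot <- cnt[, .(n = sum(count)), by = library_id]
  expect_equal(tot[library_id == "pos", n], 4000L)
  expect_equal(tot[library_id == "neg", n], 2000L)
  # progeny fraction: weights prop to a*theta = (0.4, 0.1) -> 80% lineage v1
  p1 <- cnt[library_id == "pos" & lineage_id == "v1", count] / 4000
  expect_lt(abs(p1 - 0.8), 0.03)   # ~3 binomial sd at n = 4000
  # pre-existing: weights prop to a*(1-theta) = (0.1, 0.4) -> 20% lineage v1
  n1 <- cnt[library_id == "neg" & lineage_id == "v1", count] / 2000
  expect_lt(abs(n1 - 0.2), 0.03)   # ~3 binomial sd at n = 2000
})

test_that("all-theta-one community cannot fill a pre-existing library", {
  spec <- small_spec(theta = c(1, 1), seed = 2)
  expect_error(simulate_sorting(spec, seed = 2),
               "degenerate community.*pre_existing")
})

test_that("degenerate length distribution gives constant contig lengths", {
  spec <- small_spec(seed = 9, length_log_mean = log(3000), length_log_sd = 0)
  sim <- simulate_community(spec)
  expect_true(all(sim$contigs$length_bp == 3000L))
})

test_that("single-lineage theta=0.5 world recovers ratio 0.5 over replicates", {
  ratios <- vapply(1:10, function(s) {
    spec <- community_spec(
      list(lineage_spec("v1", "viral", 1, turnover_theta = 0.5)),
      list(sorted_library("pos", "viral_progeny", 100000L, site = "s1"),
           sorted_library("neg", "pre_existing_viruses", 50000L, site = "s1")),
      contig_yield = 0.005, seed = s
    )
    sim <- simulate_community(spec)
    n <- sim$contigs[, .N, by = library_id]
    progeny_ratio(n[library_id == "pos", N], n[library_id == "neg", N],
                  100000, 50000)
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.02)
})

test_that("noise-free evidence gives a perfect viral-calling round trip", {
  spec <- small_spec(seed = 31, detector_sensitivity = 1, detector_fpr = 0)
  sim <- simulate_community(spec)
  called <- call_viral(sim$contigs, sim$evidence, count_confirmed(sim$hits))
  expect_identical(called$verdict == "viral", called$true_viral)
})

test_that("detector-noise recall follows the 2-of-3 binomial tail", {
  # sensitivity 0.9, quorum 2 of 3: recall = 0.9^3 + 3 * 0.9^2 * 0.1 = 0.972
  spec <- small_spec(seed = 41, detector_sensitivity = 0.9, detector_fpr = 0,
                     depth_pos = 70000L, depth_neg = 35000L)
  sim <- simulate_community(spec)   # ~5000 contigs
  expect_gte(nrow(sim$contigs), 5000)
  called <- call_viral(sim$contigs, sim$evidence, count_confirmed(sim$hits))
  recall <- called[true_viral == TRUE, mean(verdict == "viral")]
  expect_equal(recall, 0.972, tolerance = 0.01)
})
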