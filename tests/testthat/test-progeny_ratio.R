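test_that("ratio formula: boundaries, equal depths, scale invariance", {
  expect_equal(progeny_ratio(7, 0, 1e5, 5e4), 1)
  expect_equal(progeny_ratio(0, 7, 1e5, 5e4), 0)
  expect_equal(progeny_ratio(10, 10, 2e4, 2e4), 0.5)
  expect_true(is.na(progeny_ratio(0, 0, 1e5, 5e4)))
  expect_error(progeny_ratio(1, 1, 0, 5e4), "depths")
  # equal depths reduce to the raw proportion
  for (n in list(c(3, 9), c(120, 7), c(1, 1))) {
    expect_equal(progeny_ratio(n[1], n[2], 777, 777), n[1] / sum(n))
  }
  # scale invariance in the depths
  for (cc in c(0.001, 1, 42, 1e6)) {
    expect_equal(progeny_ratio(15, 2, 1e5 * cc, 5e4 * cc),
                 progeny_ratio(15, 2, 1e5, 5e4))
  }
})

test_that("ratio is monotone: increasing in n_pos, decreasing in n_neg", {
  base <- progeny_ratio(10, 10, 1e5, 5e4)
  expect_gt(progeny_ratio(11, 10, 1e5, 5e4), base)
  expect_lt(progeny_ratio(10, 11, 1e5, 5e4), base)
  r <- progeny_ratio(0:50, 50:0, 1e5, 5e4)
  expect_true(all(diff(r) > 0))
})

test_that("printed cluster percentages arise from unique integer splits", {
  # (size, printed %) -> the enumeration oracle must find exactly one split
  cases <- list(c(17, 78.95, 15), c(199, 82.57, 180), c(78, 65.96, 62))
  for (cs in cases) {
    hits <- enumerate_ratio_splits(cs[1], 1e5, 5e4, cs[2])
    expect_equal(hits, cs[3])
    expect_equal(progeny_ratio_pct(cs[3], cs[1] - cs[3], 1e5, 5e4), cs[2])
  }
})

test_that("half-up rounding matches printed precision", {
  expect_equal(round_half_up(78.94736, 2), 78.95)
  expect_equal(round_half_up(2.45, 1), 2.5)
  expect_equal(round_half_up(33.8107, 1), 33.8)
  expect_equal(round_half_up(74.36, 0), 74)
})

test_that("bootstrap interval behaviour", {
  # no variability: degenerate interval at 1
  ci <- bootstrap_ci(200, 0, 1e5, 5e4, n_boot = 500, seed = 1)
  expect_equal(unname(ci), c(1, 1))
  # the point estimate sits inside its own bootstrap interval
  ci <- bootstrap_ci(15, 2, 1e5, 5e4, n_boot = 10000, seed = 1)
  expect_lte(ci[["ci_low"]], 0.789)
  expect_gte(ci[["ci_high"]], 0.790)
  # deterministic under seed
  expect_identical(bootstrap_ci(15, 2, 1e5, 5e4, seed = 5),
                   bootstrap_ci(15, 2, 1e5, 5e4, seed = 5))
  expect_warning(bootstrap_ci(5, 5, 1, 1, n_boot = 50, seed = 1), "n_boot")
})

test_that("cluster ratios pool by sign, exclude cell fractions, report reasons", {
  libraries <- data.table::data.table(
    library_id = c("pos", "neg", "act", "med_pos"),
    site = c("s1", "s1", "s1", "s2"),
    fraction = c("viral_progeny", "pre_existing_viruses", "active_cells",
                 "viral_progeny"),
    sorted_depth = c(100000L, 50000L, 25000L, 41000L)
  )
  clusters <- data.table::data.table(
    cluster_id = c(rep("VC_1", 17), rep("VC_2", 3), rep("VC_3", 2)),
    member = paste0("m", 1:22),
    is_reference = FALSE
  )
  meta <- data.table::data.table(
    contig_id = paste0("m", 1:22),
    library_id = c(rep("pos", 15), rep("neg", 2),  # VC_1: the 15/2 split
                   rep("act", 3),                  # VC_2: cells only
                   rep("med_pos", 2))              # VC_3: site without neg sort
  )
  out <- cluster_ratios(clusters, meta, libraries, n_boot = 200, seed = 3)
  vc1 <- out[cluster_id == "VC_1"]
  expect_equal(vc1$ratio_pct, 78.95)
  expect_equal(vc1$reason, "ok")
  expect_true(vc1$ci_low <= vc1$ratio & vc1$ratio <= vc1$ci_high)
  expect_equal(out[cluster_id == "VC_2", reason], "no viral-fraction members")
  expect_true(is.na(out[cluster_id == "VC_2", ratio]))
  expect_equal(out[cluster_id == "VC_3", reason], "no negative viral library")
  # with cross-site pooling the progeny-only site enters the counts
  pooled <- cluster_ratios(clusters, meta, libraries, pool_sites = TRUE,
                           n_boot = 200, seed = 3)
  expect_equal(pooled[cluster_id == "VC_3", n_pos], 2L)
  expect_equal(pooled[cluster_id == "VC_3", reason], "ok")
  # unknown member library is a data error
  bad <- data.table::copy(meta)[1, library_id := "mystery"]
  expect_error(cluster_ratios(clusters, bad, libraries), "library")
})

test_that("synthetic theta=0.5 cluster lands near 0.5 at binomial precision", {
  set.seed(99)
  # 300 members, each positive w.p. D_pos/(D_pos+D_neg) = 2/3 so that the
  # depth-normalised ratio has expectation 0.5
  n <- 300
  npos <- rbinom(1, n, 2 / 3)
  r <- progeny_ratio(npos, n - npos, 1e5, 5e4)
  expect_equal(r, 0.5, tolerance = 0.12)  # 0.5 +/- 0.06 absolute
})
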