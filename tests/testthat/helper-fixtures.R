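# Fixture builders shared across test files. Everything is generated in
# code; no binary data ships with the package.

# a contig table with exact per-library marginals (assembled, assembled
# >=5kb, viral, viral >=1.5kb, viral >=5kb), used to feed summarize_fractions
# with the counts printed in per-population sorting summaries
contig_fixture <- function(library_id, assembled, assembled_5kb, viral,
                           viral_1500, viral_5kb) {
  v_below <- viral - viral_1500
  v_mid <- viral_1500 - viral_5kb
  nv <- assembled - viral
  nv_5kb <- assembled_5kb - viral_5kb
  nv_below <- nv - nv_5kb
  stopifnot(v_below >= 0, v_mid >= 0, nv_5kb >= 0, nv_below >= 0)
  len <- c(rep(800L, v_below), rep(2000L, v_mid), rep(6000L, viral_5kb),
           rep(800L, nv_below), rep(6000L, nv_5kb))
  verdict <- c(rep("viral", viral), rep("non_viral", nv))
  data.table::data.table(
    contig_id = sprintf("%s_f%05d", library_id, seq_along(len)),
    library_id = library_id, length_bp = len, verdict = verdict
  )
}

# the per-population sorting summary rows of the deep-sort experiment
# (assembled, assembled >=5kb, viral, viral >=1.5kb, viral >=5kb, printed %)
table1_rows <- list(
  list("Viral progeny",       21141L, 1606L, 1584L, 960L, 543L, 33.8),
  list("Pre-existing viruses", 5962L,  500L,  831L, 500L, 287L, 57.4),
  list("Active cells",         6121L,  407L,  821L, 535L, 313L, 76.9),
  list("Non-active cells",     7323L,  699L,   47L,  31L,  17L,  2.4),
  list("MS Viral progeny 6h",   787L,   29L,  667L,  66L,  24L, 82.8),
  list("MS Viral progeny 30m",  679L,   69L,  476L,  77L,  39L, 56.5),
  list("MS Active cells",       230L,    4L,  218L,  23L,   4L, 100.0)
)

# a tiny two-viral-lineage community cheap enough for unit tests
small_spec <- function(seed = 7L, theta = c(0.8, 0.2), depth_pos = 4000L,
                       depth_neg = 2000L, ...) {
  nv <- length(theta)
  viral <- lapply(seq_len(nv), function(i) {
    lineage_spec(paste0("v", i), "viral", relative_abundance = 1 / nv,
                 turnover_theta = theta[i], genome_length_bp = 40000L,
                 n_proteins = 25L, protein_divergence = 0.05)
  })
  libs <- list(
    sorted_library("pos", "viral_progeny", depth_pos, site = "s1"),
    sorted_library("neg", "pre_existing_viruses", depth_neg, site = "s1")
  )
  community_spec(viral, libs, contig_yield = 0.05, seed = seed, ...)
}

# random hit table with query lengths, for property tests of the filters
random_hits <- function(n, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    query_id = sprintf("c%03d|p%d", sample(40, n, TRUE), sample(5, n, TRUE)),
    subject_id = sprintf("ref%03d", sample(50, n, TRUE)),
    pct_identity = round(runif(n, 40, 100), 2),
    aln_length = sample(50:400, n, TRUE),
    mismatches = sample(0:50, n, TRUE),
    gap_opens = sample(0:3, n, TRUE),
    qstart = 1L, qend = sample(50:400, n, TRUE),
    sstart = 1L, send = sample(50:400, n, TRUE),
    evalue = 10^-runif(n, 0, 180),
    bitscore = round(runif(n, 30, 900), 1),
    query_length = sample(100:400, n, TRUE)
  )
}
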