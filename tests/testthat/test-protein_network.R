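test_that("hypergeometric tail matches exhaustive enumeration for M <= 12", {
  set.seed(1)
  for (rep in 1:40) {
    M <- sample(3:12, 1)
    a <- sample(1:M, 1); b <- sample(1:M, 1)
    c <- sample(0:min(a, b), 1)
    got <- hypergeom_edge(c, a, b, M)
    expect_equal(got$p_value, enum_hyper_tail(c, a, b, M), tolerance = 1e-12,
                 info = sprintf("c=%d a=%d b=%d M=%d", c, a, b, M))
  }
})

test_that("hypergeometric edge cases and the 22/120 worked example", {
  # c = 0: the tail covers everything
  expect_equal(hypergeom_edge(0, 3, 4, 10)$p_value, 1)
  expect_equal(hypergeom_edge(0, 3, 4, 10)$weight, 0)
  # forced full overlap is certain
  expect_equal(hypergeom_edge(5, 5, 5, 5)$p_value, 1)
  # a=3, b=3, M=10, c=2: (3*7 + 1) / C(10,3) = 22/120
  expect_equal(hypergeom_edge(2, 3, 3, 10)$p_value, 22 / 120, tolerance = 1e-12)
  # weight capped at 300 for vanishing p
  expect_lte(hypergeom_edge(300, 300, 300, 1e6)$weight, 300)
  # domain error
  expect_error(hypergeom_edge(4, 3, 3, 10), "c <= min")
})

test_that("MCL returns a partition and keeps disjoint cliques apart", {
  A <- two_clique_graph(4, bridge = FALSE)
  for (inf in c(1.5, 2, 4)) {
    memb <- mcl(A, inflation = inf)
    expect_length(memb, 8)
    expect_equal(sort(unique(memb)), 1:2)
    expect_equal(length(unique(memb[1:4])), 1)
    expect_equal(length(unique(memb[5:8])), 1)
  }
  # single edge -> one cluster
  e <- data.table::data.table(from = "a", to = "b", weight = 1)
  A1 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(mcl(A1)), c(1L, 1L))
  # non-symmetric input is a graph error
  bad <- matrix(c(0, 1, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(mcl(bad), "symmetric")
})

test_that("MCL matches a naive reference implementation on small graphs", {
  # bridged two-clique graph: the classic 2-cluster case at inflation 2
  A <- two_clique_graph(4, bridge = TRUE)
  got <- mcl(A, inflation = 2)
  ref <- naive_mcl(A, inflation = 2)
  expect_true(same_partition(got, ref))
  expect_equal(length(unique(got)), 2)

  # random sparse graphs, several seeds
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10
    A <- matrix(0, n, n, dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
    nedge <- 14
    idx <- sample(which(upper.tri(A)), nedge)
    A[idx] <- runif(nedge, 0.5, 2)
    A <- A + t(A)
    expect_true(same_partition(mcl(A), naive_mcl(A)),
                info = paste("seed", seed))
  }
})

test_that("MCL near inflation 1 reduces to connected components", {
  set.seed(4)
  for (rep in 1:3) {
    n <- 9
    A <- matrix(0, n, n, dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
    idx <- sample(which(upper.tri(A)), 10)
    A[idx] <- 1
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    comp <- igraph::components(g)$membership
    memb <- mcl(A, inflation = 1.01, max_iter = 200)
    expect_true(same_partition(memb, comp))
  }
})

test_that("node input order does not change the MCL partition", {
  set.seed(8)
  n <- 12
  A <- matrix(0, n, n, dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
  idx <- sample(which(upper.tri(A)), 20)
  A[idx] <- runif(20, 0.5, 3)
  A <- A + t(A)
  ref <- mcl(A)
  for (rep in 1:3) {
    p <- sample(n)
    got <- mcl(A[p, p])
    expect_true(same_partition(got, ref))
  }
})

test_that("protein clustering covers the universe disjointly", {
  edges <- data.table::data.table(
    from = c("p1", "p2", "p4"), to = c("p2", "p3", "p5"), weight = c(5, 5, 2))
  pcs <- cluster_proteins(edges, proteins = paste0("p", 1:6))
  expect_setequal(pcs$protein_id, paste0("p", 1:6))
  expect_equal(anyDuplicated(pcs$protein_id), 0)
  # p6 has no edges: its own singleton PC
  expect_equal(sum(pcs$pc_id == pcs[protein_id == "p6", pc_id]), 1)
  expect_error(cluster_proteins(
    data.table::data.table(from = "a", to = "b", weight = -1)), "> 0")
})

test_that("network edges appear exactly when the hypergeometric tail is small", {
  # no shared PCs -> no edges
  gp <- data.table::data.table(genome_id = c("g1", "g1", "g2", "g2"),
                               pc_id = c("A", "B", "C", "D"))
  net <- build_network(c("g1", "g2"), gp, min_weight = 1)
  expect_equal(nrow(net), 0)

  # identical repertoires -> strong edge
  gp <- data.table::data.table(genome_id = rep(c("g1", "g2"), each = 4),
                               pc_id = rep(c("A", "B", "C", "D"), 2))
  net <- build_network(c("g1", "g2"), gp, min_weight = 1, M = 40)
  expect_equal(nrow(net), 1)
  expect_equal(net$shared_pcs, 4L)

  # 3 genomes sharing a 5-PC core in a universe of 50: all pairwise edges,
  # p from the enumeration identity p = C(45,5)/C(50,10)-style tail < 0.1
  gp <- data.table::rbindlist(lapply(1:3, function(g) data.table::data.table(
    genome_id = paste0("g", g),
    pc_id = c(paste0("core", 1:5), paste0("own", g, "_", 1:3)))))
  net <- build_network(paste0("g", 1:3), gp, min_weight = 1, M = 50)
  expect_equal(nrow(net), 3)
  expect_true(all(net$weight >= 1))
  # zero-protein genome excluded with a warning
  expect_warning(build_network(c("g1", "g2", "g3", "gz"), gp, M = 50),
                 "zero protein")
})

test_that("genome clustering recovers planted lineages exactly (ARI = 1)", {
  spec <- small_spec(seed = 23, theta = c(0.7, 0.3))
  sim <- simulate_community(spec)
  called <- call_viral(sim$contigs, sim$evidence, count_confirmed(sim$hits))
  net_ids <- called[verdict == "viral" & length_bp >= 5000, contig_id]
  hits_net <- sim$hits[protein_to_contig(query_id) %in% net_ids]
  pcs <- cluster_proteins(protein_edges_from_hits(hits_net),
                          proteins = unique(hits_net$query_id))
  gp <- data.table::data.table(genome_id = protein_to_contig(pcs$protein_id),
                               pc_id = pcs$pc_id)
  net <- build_network(net_ids, gp)
  clus <- cluster_genomes(net)
  truth <- setNames(sim$contigs$lineage_id, sim$contigs$contig_id)[clus$member]
  ari <- igraph::compare(as.integer(factor(clus$cluster_id)),
                         as.integer(factor(truth)), method = "adjusted.rand")
  expect_equal(ari, 1)
  # partition: every network node in exactly one cluster
  expect_setequal(clus$member, attr(net, "nodes"))
  expect_equal(anyDuplicated(clus$member), 0)
})

test_that("singletons and empty networks are handled", {
  empty <- data.table::data.table(i = character(0), j = character(0),
                                  shared_pcs = integer(0),
                                  p_value = numeric(0), weight = numeric(0))
  expect_equal(nrow(cluster_genomes(empty)), 0)
  clus <- cluster_genomes(empty, nodes = c("solo1", "solo2"))
  expect_equal(nrow(clus), 2)
  expect_equal(length(unique(clus$cluster_id)), 2)
})
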