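#' Hypergeometric significance of shared protein clusters between two genomes
#'
#' Probability of observing `c` or more shared protein clusters (PCs) between
#' a genome with `a` PCs and one with `b` PCs when both draw independently
#' from a universe of `M` PCs:
#' \deqn{p = \sum_{k=c}^{\min(a,b)} \binom{a}{k}\binom{M-a}{b-k} / \binom{M}{b}}
#' computed in log-space. The edge weight is `-log10(p)` with `p` floored at
#' 1e-300 and the weight capped at 300, the convention of gene-sharing
#' network tools.
#'
#' @param c shared PC count (vectorised).
#' @param a,b PC counts of the two genomes (vectorised).
#' @param M total number of PCs in the universe.
#' @return `data.table` with `p_value` and `weight`.
#' @export
hypergeom_edge <- function(c, a, b, M) {
  n <- max(length(c), length(a), length(b))
  c <- rep_len(as.numeric(c), n); a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  if (any(c < 0) || any(c > pmin(a, b)) || any(pmax(a, b) > M)) {
    stop("require 0 <= c <= min(a, b) <= M", call. = FALSE)
  }
  logp <- vapply(seq_len(n), function(i) {
    k <- seq(c[i], min(a[i], b[i]))
    logsumexp(lchoose(a[i], k) + lchoose(M - a[i], b[i] - k) - lchoose(M, b[i]))
  }, numeric(1))
  p <- pmin(exp(logp), 1)
  p <- pmax(p, 1e-300)
  data.table(p_value = p, weight = pmin(-log10(p), 300))
}

#' Cluster proteins into protein clusters (PCs) with MCL
#'
#' Builds the protein similarity graph from a weighted edge list (by default
#' bit-score weights on hits filtered at e-value <= 1e-5) and partitions it
#' with [mcl()]. Singleton proteins become singleton PCs, so the result is a
#' partition of the full protein universe.
#'
#' @param edges data.frame with columns `from`, `to`, `weight` (protein ids
#'   and positive similarity weights).
#' @param proteins optional character vector of all protein ids, so proteins
#'   without any edge still receive a (singleton) PC.
#' @param inflation MCL inflation (default 2.0).
#' @param ... further arguments passed to [mcl()].
#' @return `data.table` with `protein_id` and `pc_id` (`"PC_<k>"`).
#' @export
cluster_proteins <- function(edges, proteins = NULL, inflation = 2.0, ...) {
  if (nrow(edges) > 0 && any(edges[[3]] <= 0)) {
    stop("protein similarity weights must be > 0", call. = FALSE)
  }
  memb <- mcl_edges(edges, nodes = proteins, inflation = inflation, ...)
  data.table(protein_id = names(memb),
             pc_id = sprintf("PC_%05d", memb))
}

#' Build the protein-sharing genome network
#'
#' Nodes are genomes/contigs (the >=5 kb networking tier, plus any reference
#' genomes); an edge between two genomes carries the number of shared PCs and
#' its hypergeometric significance from [hypergeom_edge()]. Edges are kept
#' when `weight >= min_weight` (default 1, i.e. p <= 0.1). Genomes with no
#' protein clusters are excluded with a warning, not an error.
#'
#' @param genome_ids character vector of node ids to include.
#' @param genome_pcs data.frame with `genome_id`, `pc_id` (one row per
#'   genome/PC incidence; duplicates are collapsed).
#' @param min_weight minimum edge weight retained.
#' @param M total PC universe size; defaults to the number of distinct PCs
#'   in `genome_pcs`.
#' @return `data.table` of edges (`i`, `j`, `shared_pcs`, `p_value`,
#'   `weight`) with `i < j` lexicographically; node set in attribute
#'   `"nodes"`.
#' @export
build_network <- function(genome_ids, genome_pcs, min_weight = 1, M = NULL) {
  genome_pcs <- unique(as.data.table(genome_pcs)[, .(genome_id, pc_id)])
  genome_ids <- sort(unique(as.character(genome_ids)))
  if (is.null(M)) M <- length(unique(genome_pcs$pc_id))
  empty_nodes <- setdiff(genome_ids, unique(genome_pcs$genome_id))
  if (length(empty_nodes)) {
    warning(length(empty_nodes), " genome(s) with zero protein clusters ",
            "excluded from the network (e.g. '", empty_nodes[1], "')",
            call. = FALSE)
  }
  nodes <- setdiff(genome_ids, empty_nodes)
  gp <- genome_pcs[genome_id %in% nodes]
  pcs <- sort(unique(gp$pc_id))
  inc <- matrix(0L, length(nodes), length(pcs), dimnames = list(nodes, pcs))
  inc[cbind(match(gp$genome_id, nodes), match(gp$pc_id, pcs))] <- 1L
  shared <- tcrossprod(inc)
  a <- rowSums(inc)
  pair <- which(upper.tri(shared) & shared >= 1, arr.ind = TRUE)
  if (nrow(pair) == 0) {
    edges <- data.table(i = character(0), j = character(0),
                        shared_pcs = integer(0), p_value = numeric(0),
                        weight = numeric(0))
  } else {
    cij <- shared[pair]
    ai <- a[pair[, 1]]; bj <- a[pair[, 2]]
    # p depends only on (c, a, b); deduplicate before the log-space sum
    key <- paste(cij, pmin(ai, bj), pmax(ai, bj))
    uk <- !duplicated(key)
    hv <- hypergeom_edge(cij[uk], ai[uk], bj[uk], M)
    idx <- match(key, key[uk])
    edges <- data.table(i = nodes[pair[, 1]], j = nodes[pair[, 2]],
                        shared_pcs = as.integer(cij),
                        p_value = hv$p_value[idx], weight = hv$weight[idx])
    edges <- edges[weight >= min_weight]
    setorder(edges, i, j)
  }
  log_stage("build_network", length(genome_ids), nrow(edges))
  data.table::setattr(edges, "nodes", nodes)
  edges[]
}

#' Partition the genome network into viral clusters with MCL
#'
#' Reference genomes are carried as nodes but flagged so that downstream
#' per-library counting excludes them. Clusters are labelled `"VC_<k>"` by
#' decreasing size with deterministic tie-breaking; nodes without any edge
#' form singleton clusters.
#'
#' @param network edge table from [build_network()] (or any `i`, `j`,
#'   `weight` edge list).
#' @param nodes node universe; defaults to the network's `"nodes"` attribute
#'   or the union of edge endpoints.
#' @param reference_ids node ids to flag as reference genomes.
#' @param inflation MCL inflation (default 2.0).
#' @param ... further arguments passed to [mcl()].
#' @return `data.table` with `cluster_id`, `member`, `is_reference`.
#' @export
cluster_genomes <- function(network, nodes = NULL, reference_ids = character(),
                            inflation = 2.0, ...) {
  network <- as.data.table(network)
  if (is.null(nodes)) nodes <- attr(network, "nodes")
  if (is.null(nodes)) nodes <- unique(c(network$i, network$j))
  if (length(nodes) == 0) {
    return(data.table(cluster_id = character(0), member = character(0),
                      is_reference = logical(0)))
  }
  edges <- network[, .(from = i, to = j, weight = weight)]
  memb <- mcl_edges(edges, nodes = nodes, inflation = inflation, ...)
  out <- data.table(cluster_id = sprintf("VC_%d", memb), member = names(memb),
                    is_reference = names(memb) %in% reference_ids)
  setorder(out, cluster_id, member)
  out[]
}

#' Per-library member counts of viral clusters
#'
#' @param clusters output of [cluster_genomes()].
#' @param contig_meta data.frame mapping `contig_id` to `library_id`.
#' @return `data.table` with `cluster_id`, `library_id`, `count` (reference
#'   members excluded).
#' @export
count_cluster_libraries <- function(clusters, contig_meta) {
  clusters <- as.data.table(clusters)[is_reference == FALSE]
  meta <- as.data.table(contig_meta)
  dt <- merge(clusters, meta[, .(contig_id, library_id)],
              by.x = "member", by.y = "contig_id", all.x = TRUE)
  if (anyNA(dt$library_id)) {
    stop("cluster member '", dt$member[is.na(dt$library_id)][1],
         "' has no known library", call. = FALSE)
  }
  dt[, .(count = .N), by = .(cluster_id, library_id)][order(cluster_id, library_id)]
}
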