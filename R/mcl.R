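#' Markov Cluster (MCL) algorithm on a weighted undirected graph
#'
#' Native implementation of flow-based graph clustering: the column-stochastic
#' transition matrix is alternately expanded (matrix power, default 2) and
#' inflated (entrywise power followed by column renormalisation) until the
#' matrix stops changing. Clusters are the connected components of the
#' converged attractor matrix. Self-loops are added at each node's maximum
#' incident edge weight (1 for isolated nodes) before normalisation, the
#' standard regularisation. Entries below `prune_floor` are dropped each
#' iteration for tractability; this is a numerical, not semantic, parameter.
#'
#' The graph is processed one connected component at a time (flow never
#' crosses components, so this is exact) and the result does not depend on
#' node input order: clusters are labelled by decreasing size with ties
#' broken by the lexicographically smallest member id.
#'
#' @param adjacency square symmetric numeric matrix with non-negative
#'   weights and dimnames, zero diagonal expected.
#' @param inflation inflation exponent (> 1; default 2.0).
#' @param expansion expansion power (integer >= 2; default 2).
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence threshold on the maximum entrywise change.
#' @param prune_floor entries below this are zeroed each iteration.
#' @return integer membership vector named by node id; cluster 1 is the
#'   largest.
#' @export
mcl <- function(adjacency, inflation = 2.0, expansion = 2L, max_iter = 100L,
                tol = 1e-6, prune_floor = 1e-6) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(adjacency))) {
    rownames(adjacency) <- colnames(adjacency) <- paste0("n", seq_len(nrow(adjacency)))
  }
  if (max(abs(adjacency - t(adjacency))) > 1e-8) {
    stop("adjacency must be symmetric (undirected graph)", call. = FALSE)
  }
  if (any(adjacency < 0)) stop("edge weights must be non-negative", call. = FALSE)
  n <- nrow(adjacency)
  if (n == 0) return(setNames(integer(0), character(0)))

  # canonical node order makes the result input-order invariant
  ord <- order(rownames(adjacency))
  A <- adjacency[ord, ord, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)$membership
  membership <- integer(n)
  names(membership) <- rownames(A)
  next_id <- 0L
  for (cid in sort(unique(comp))) {
    nodes <- names(comp)[comp == cid]
    sub <- A[nodes, nodes, drop = FALSE]
    labs <- mcl_component(sub, inflation, expansion, max_iter, tol, prune_floor)
    membership[nodes] <- labs + next_id
    next_id <- next_id + max(labs)
  }
  relabel_clusters(membership)
}

# MCL on a single connected component (dense within the component; flow
# never crosses components, so per-component processing is exact and keeps
# the matrices small)
mcl_component <- function(A, inflation, expansion, max_iter, tol, prune_floor) {
  n <- nrow(A)
  if (n == 1) return(setNames(1L, rownames(A)))
  loops <- apply(A, 2, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  col_scale <- function(X) {
    cs <- colSums(X)
    dead <- cs == 0          # fully pruned column: park the node on itself
    if (any(dead)) {
      X[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    sweep(X, 2, cs, "/")
  }
  M <- col_scale(A)
  for (iter in seq_len(max_iter)) {
    E <- M
    for (e in seq_len(expansion - 1L)) E <- E %*% M
    E <- E^inflation
    E[E < prune_floor] <- 0
    E <- col_scale(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) break
  }
  keep <- M > prune_floor
  adj <- keep | t(keep)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  setNames(as.integer(igraph::components(g)$membership), rownames(A))
}

# MCL on an edge list: split into connected components first and only then
# build the (small) dense matrix of each component, so large sparse graphs
# never materialise a full adjacency matrix
mcl_edges <- function(edges, nodes = NULL, inflation = 2.0, expansion = 2L,
                      max_iter = 100L, tol = 1e-6, prune_floor = 1e-6) {
  edges <- as.data.table(edges)
  if (ncol(edges) < 3) stop("edges need from, to, weight columns", call. = FALSE)
  data.table::setnames(edges, 1:3, c("from", "to", "weight"))
  edges[, `:=`(from = as.character(from), to = as.character(to))]
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  nodes <- sort(unique(as.character(nodes)))
  if (length(nodes) == 0) return(setNames(integer(0), character(0)))
  g <- igraph::graph_from_data_frame(edges[, .(from, to)], directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)$membership
  membership <- setNames(integer(length(nodes)), nodes)
  edge_comp <- comp[edges$from]
  next_id <- 0L
  for (cid in sort(unique(comp))) {
    members <- sort(names(comp)[comp == cid])
    if (length(members) == 1) {
      membership[members] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    sub <- edges[edge_comp == cid]
    A <- matrix(0, length(members), length(members),
                dimnames = list(members, members))
    i <- match(sub$from, members); j <- match(sub$to, members)
    A[cbind(i, j)] <- pmax(A[cbind(i, j)], sub$weight)
    A[cbind(j, i)] <- pmax(A[cbind(j, i)], sub$weight)
    diag(A) <- 0
    labs <- mcl_component(A, inflation, expansion, max_iter, tol, prune_floor)
    membership[members] <- labs + next_id
    next_id <- next_id + max(labs)
  }
  relabel_clusters(membership)
}

# deterministic labels: by decreasing size, ties by smallest member id
relabel_clusters <- function(membership) {
  ids <- names(membership)
  sizes <- table(membership)
  firsts <- vapply(split(ids, membership), function(m) min(m), character(1))
  o <- order(-as.integer(sizes[names(firsts)]), firsts)
  new_lab <- setNames(seq_along(o), names(firsts)[o])
  out <- as.integer(new_lab[as.character(membership)])
  names(out) <- ids
  out
}

# build a dense adjacency matrix from an edge list (from, to, weight)
edges_to_adjacency <- function(edges, nodes = NULL) {
  edges <- as.data.table(edges)
  data.table::setnames(edges, 1:3, c("from", "to", "weight"))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  nodes <- sort(unique(as.character(nodes)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    i <- match(edges$from, nodes); j <- match(edges$to, nodes)
    A[cbind(i, j)] <- pmax(A[cbind(i, j)], edges$weight)
    A[cbind(j, i)] <- pmax(A[cbind(j, i)], edges$weight)
  }
  diag(A) <- 0
  A
}
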