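# Independent oracles used across the suite. These are deliberately naive
# (enumeration, loops) and share no code with the package implementation.

# hypergeometric upper tail by literal enumeration of all size-b subsets of
# a universe with `a` marked elements; tractable for M <= 12
enum_hyper_tail <- function(c, a, b, M) {
  subsets <- utils::combn(M, b)
  marked <- seq_len(a)
  overlaps <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(overlaps >= c)
}

# naive reference MCL: dense, loop-based column operations, no pruning
naive_mcl <- function(A, inflation = 2, max_iter = 200, tol = 1e-9) {
  n <- nrow(A)
  for (j in seq_len(n)) A[j, j] <- max(A[, j])
  for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
  for (it in seq_len(max_iter)) {
    E <- A %*% A
    for (j in seq_len(n)) {
      col <- E[, j]^inflation
      E[, j] <- col / sum(col)
    }
    if (max(abs(E - A)) < tol) { A <- E; break }
    A <- E
  }
  link <- (A > 1e-8) | t(A > 1e-8)
  diag(link) <- TRUE
  # connected components by BFS
  lab <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(lab[v])) next
      lab[v] <- k
      queue <- c(queue, which(link[v, ] & is.na(lab)))
    }
  }
  setNames(lab, rownames(A))
}

# partitions agree up to label permutation
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# adjacency matrix of two k-cliques, optionally joined by one unit edge
two_clique_graph <- function(k = 4, bridge = FALSE, w = 1) {
  n <- 2 * k
  A <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  A[1:k, 1:k] <- w
  A[(k + 1):n, (k + 1):n] <- w
  diag(A) <- 0
  if (bridge) A["n1", paste0("n", k + 1)] <- A[paste0("n", k + 1), "n1"] <- 1
  A
}

# additive distance matrix from a known 4-taxon tree:
#   ((a:2,b:3):1,(c:4,d:5))  ->  unique additive metric
additive_4taxon <- function() {
  d <- matrix(0, 4, 4, dimnames = list(c("a", "b", "c", "d"),
                                       c("a", "b", "c", "d")))
  bl <- c(a = 2, b = 3, c = 4, d = 5)
  internal <- 1
  d["a", "b"] <- d["b", "a"] <- bl["a"] + bl["b"]
  d["c", "d"] <- d["d", "c"] <- bl["c"] + bl["d"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    d[x, y] <- d[y, x] <- bl[x] + bl[y] + internal
  }
  d
}
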