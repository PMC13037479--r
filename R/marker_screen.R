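#' Screen proteins for gp23-like Far-T4 marker hits
#'
#' Keeps, for every query protein, its best reference hit (highest bit
#' score; ties broken by smallest e-value, then lexicographic reference id)
#' and flags it as passing under the published marker thresholds, which are
#' strict inequalities: bit score > 50 AND e-value < 1e-10. A hit at exactly
#' bit score 50 or e-value 1e-10 fails.
#'
#' @param hits hit table ([read_hits()] columns; `query_length` not needed).
#' @param min_bitscore bit-score threshold (exclusive; default 50).
#' @param max_evalue e-value threshold (exclusive; default 1e-10).
#' @return `data.table` with `protein_id`, `contig_id`, `reference_id`,
#'   `bitscore`, `evalue`, `passes`; one row per query protein.
#' @export
screen_markers <- function(hits, min_bitscore = 50, max_evalue = 1e-10) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0) {
    return(data.table(protein_id = character(0), contig_id = character(0),
                      reference_id = character(0), bitscore = numeric(0),
                      evalue = numeric(0), passes = logical(0)))
  }
  best <- hits[order(query_id, -bitscore, evalue, subject_id),
               .SD[1], by = query_id]
  out <- best[, .(protein_id = query_id,
                  contig_id = protein_to_contig(query_id),
                  reference_id = subject_id, bitscore, evalue)]
  out[, passes := bitscore > min_bitscore & evalue < max_evalue]
  out[]
}

#' Filter host-linkage candidates at the published stringent thresholds
#'
#' A candidate genome pair passes when all three axes hold simultaneously
#' (inclusive thresholds): shared protein fraction >= 0.80, mean amino-acid
#' identity >= 0.60 and mean coverage >= 0.95. Shared fraction is measured
#' relative to the query genome's protein count; identity is the mean over
#' the shared proteins.
#'
#' @param candidates data.frame with `query_genome`, `reference_genome`,
#'   `shared_protein_fraction`, `mean_aai`, `mean_coverage` (all fractions
#'   in \[0, 1\]).
#' @param min_shared,min_aai,min_cov inclusive thresholds.
#' @param keep_all return all candidates with a `passes` column instead of
#'   only the passing rows.
#' @return `data.table` of passing candidates (or all, with `passes`).
#' @export
host_link_filter <- function(candidates, min_shared = 0.80, min_aai = 0.60,
                             min_cov = 0.95, keep_all = FALSE) {
  cand <- as.data.table(candidates)
  for (f in c("shared_protein_fraction", "mean_aai", "mean_coverage")) {
    check_prob(cand[[f]], f)
  }
  cand[, passes := shared_protein_fraction >= min_shared &
         mean_aai >= min_aai & mean_coverage >= min_cov]
  if (keep_all) cand[] else cand[passes == TRUE][]
}

#' Pairwise p-distances between pre-aligned sequences
#'
#' Position-by-position comparison on equal-length aligned sequences:
#' mismatches divided by shared non-gap positions (`-` is the gap
#' character). Pairs with no shared non-gap position get distance 0.
#'
#' @param sequences named character vector of aligned sequences (equal
#'   length).
#' @return symmetric numeric distance matrix.
#' @export
p_distance <- function(sequences) {
  n <- length(sequences)
  if (is.null(names(sequences))) names(sequences) <- paste0("s", seq_len(n))
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      shared <- sum(ok)
      d[i, j] <- d[j, i] <- if (shared == 0) 0 else
        sum(chars[i, ok] != chars[j, ok]) / shared
    }
  }
  d
}

#' Neighbor-joining tree from pre-aligned sequences
#'
#' A desk-scale stand-in for the maximum-likelihood marker phylogeny:
#' p-distances ([p_distance()]) followed by neighbor joining (the standard
#' Q-criterion, via \pkg{ape}). Negative branch lengths are clamped to 0.
#' Sequences are sorted by name before tree building, so the topology does
#' not depend on input order.
#'
#' @param sequences named character vector of >= 3 aligned sequences.
#' @param file optional path; when given the tree is also written in Newick
#'   format.
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(sequences, file = NULL) {
  if (length(sequences) < 3) {
    stop("neighbor joining needs at least 3 sequences", call. = FALSE)
  }
  sequences <- sequences[order(names(sequences))]
  tree <- nj_from_dist(p_distance(sequences))
  if (!is.null(file)) ape::write.tree(tree, file = file)
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param d symmetric distance matrix with dimnames. On an additive matrix
#'   NJ recovers the generating topology and branch lengths exactly.
#' @return an \pkg{ape} `phylo` tree with branch lengths clamped at >= 0.
#' @export
nj_from_dist <- function(d) {
  ord <- order(rownames(d))
  tree <- ape::nj(d[ord, ord, drop = FALSE])
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
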