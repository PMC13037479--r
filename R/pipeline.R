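#' Protein-protein similarity edges from a reference hit table
#'
#' Two contig proteins are linked when they hit the same reference protein
#' (transitive evidence of homology); the edge weight is the smaller of the
#' two bit scores. Hits are filtered at `max_evalue` first (default 1e-5).
#'
#' @param hits hit table (contig proteins vs reference proteins).
#' @param max_evalue e-value filter applied before linking.
#' @return `data.table` with `from`, `to`, `weight`.
#' @export
protein_edges_from_hits <- function(hits, max_evalue = 1e-5) {
  hits <- as.data.table(hits)[evalue <= max_evalue]
  if (nrow(hits) == 0) {
    return(data.table(from = character(0), to = character(0), weight = numeric(0)))
  }
  best <- hits[order(query_id, subject_id, -bitscore),
               .SD[1], by = .(query_id, subject_id)]
  pairs <- merge(best[, .(subject_id, q1 = query_id, b1 = bitscore)],
                 best[, .(subject_id, q2 = query_id, b2 = bitscore)],
                 by = "subject_id", allow.cartesian = TRUE)[q1 < q2]
  pairs[, .(weight = max(pmin(b1, b2))), by = .(from = q1, to = q2)]
}

#' Run the full downstream pipeline on contig, evidence and hit tables
#'
#' Consensus viral calling, tiering, fraction summaries, protein clustering,
#' genome-network construction, MCL genome clustering and per-cluster
#' depth-normalised progeny ratios — the end-to-end route from sorted
#' libraries to turnover estimates.
#'
#' @param contigs contig table (`contig_id`, `library_id`, `length_bp`).
#' @param evidence long detector-evidence table.
#' @param hits reference hit table with `query_length`.
#' @param libraries data.frame of library metadata (`library_id`, `site`,
#'   `fraction`, `sorted_depth`) or a list of [sorted_library()] objects.
#' @param config a [run_config()].
#' @param reference_ids network nodes to flag as reference genomes.
#' @return list: `contigs` (with verdicts), `summary`, `multi_hit_pct`,
#'   `protein_clusters`, `network`, `clusters`, `ratios`.
#' @export
run_pipeline <- function(contigs, evidence, hits, libraries,
                         config = run_config(), reference_ids = character()) {
  if (is.list(libraries) && !is.data.frame(libraries)) {
    libraries <- rbindlist(lapply(libraries, function(lb) {
      as.data.table(lb[c("library_id", "site", "fraction", "boncat_positive",
                         "sorted_depth")])
    }))
  }
  contigs <- as.data.table(contigs)
  confirmed <- count_confirmed(hits, min_identity = config$min_identity,
                               min_coverage = config$min_coverage)
  called <- call_viral(contigs, evidence, confirmed,
                       min_detectors = config$min_detectors,
                       min_confirming = config$min_confirming_proteins)
  summary <- summarize_fractions(called,
                                 report_bp = config$contig_min_report_bp,
                                 network_bp = config$contig_min_network_bp)
  mh <- multi_hit_fraction(called, min_hits = config$min_confirming_proteins,
                           min_len = config$contig_min_report_bp)

  net_ids <- called[verdict == "viral" &
                      length_bp >= config$contig_min_network_bp, contig_id]
  net_ids <- union(net_ids, reference_ids)
  hits_net <- as.data.table(hits)[protein_to_contig(query_id) %in% net_ids]
  pedges <- protein_edges_from_hits(hits_net)
  pcs <- cluster_proteins(pedges,
                          proteins = unique(hits_net$query_id),
                          inflation = config$inflation,
                          max_iter = config$max_iter, tol = config$tol,
                          prune_floor = config$prune_floor)
  genome_pcs <- data.table(genome_id = protein_to_contig(pcs$protein_id),
                           pc_id = pcs$pc_id)
  network <- build_network(net_ids, genome_pcs, min_weight = config$min_weight)
  clusters <- cluster_genomes(network, reference_ids = reference_ids,
                              inflation = config$inflation,
                              max_iter = config$max_iter, tol = config$tol,
                              prune_floor = config$prune_floor)
  ratios <- if (nrow(clusters)) {
    cluster_ratios(clusters, called, libraries, n_boot = config$n_boot,
                   ci_level = config$ci_level, seed = config$seed)
  } else NULL
  list(contigs = called, summary = summary, multi_hit_pct = mh,
       protein_clusters = pcs, network = network, clusters = clusters,
       ratios = ratios)
}

#' Match genome clusters to ground-truth lineages
#'
#' For parameter-recovery checks on synthetic data: each cluster is assigned
#' the modal true lineage of its members, and for each lineage the largest
#' cluster assigned to it is reported alongside its estimated ratio.
#'
#' @param ratios output of [cluster_ratios()].
#' @param clusters output of [cluster_genomes()].
#' @param contig_meta contig table with `contig_id`, `lineage_id`.
#' @return `data.table` with one row per lineage present: `lineage_id`,
#'   `cluster_id`, `n_members`, `ratio`.
#' @export
lineage_cluster_ratios <- function(ratios, clusters, contig_meta) {
  clusters <- as.data.table(clusters)[is_reference == FALSE]
  meta <- as.data.table(contig_meta)
  dt <- merge(clusters, meta[, .(contig_id, lineage_id)],
              by.x = "member", by.y = "contig_id")
  modal <- dt[, .N, by = .(cluster_id, lineage_id)][
    order(cluster_id, -N, lineage_id), .SD[1], by = cluster_id]
  sizes <- dt[, .(n_members = .N), by = cluster_id]
  top <- merge(modal, sizes, by = "cluster_id")[
    order(lineage_id, -n_members), .SD[1], by = lineage_id]
  out <- merge(top, as.data.table(ratios)[, .(cluster_id, ratio)],
               by = "cluster_id")
  out[order(lineage_id), .(lineage_id, cluster_id, n_members, ratio)]
}
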