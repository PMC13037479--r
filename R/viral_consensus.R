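#' Count distinct query proteins with a confirming reference hit
#'
#' A query protein is confirmed when ANY of its hits reaches both the
#' identity and the coverage threshold (defaults: >=80 percent identity,
#' >=90 percent query coverage). A protein with several passing hits counts
#' once. Coverage is computed query-side as `aln_length / query_length`;
#' every hit must therefore carry a `query_length`.
#'
#' @param hits hit table from [read_hits()] with `query_length` attached.
#' @param min_identity minimum percent identity (inclusive).
#' @param min_coverage minimum query coverage as a fraction (inclusive).
#' @param ids if `TRUE` return the passing query ids instead of their count.
#' @return integer count of distinct passing query proteins (or a character
#'   vector of their ids).
#' @export
filter_confirming_hits <- function(hits, min_identity = 80, min_coverage = 0.90,
                                   ids = FALSE) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0) return(if (ids) character(0) else 0L)
  if (!"query_length" %in% names(hits) || anyNA(hits$query_length)) {
    bad <- if ("query_length" %in% names(hits)) {
      hits$query_id[is.na(hits$query_length)][1]
    } else hits$query_id[1]
    stop("hit for query '", bad, "' lacks query_length (needed for coverage)",
         call. = FALSE)
  }
  pass <- hits$pct_identity >= min_identity &
    (hits$aln_length / hits$query_length) >= min_coverage
  passing <- sort(unique(hits$query_id[pass]))
  if (ids) passing else length(passing)
}

#' Map protein ids to their contig of origin
#'
#' The simulator and the pipeline name contig-encoded proteins
#' `"<contig_id>|p<k>"`; this helper strips the protein suffix.
#'
#' @param protein_ids character vector of protein ids.
#' @return character vector of contig ids.
#' @export
protein_to_contig <- function(protein_ids) {
  sub("\\|p\\d+$", "", protein_ids)
}

#' Per-contig counts of confirming protein hits
#'
#' @param hits hit table with `query_length`.
#' @param proteins data.frame mapping `protein_id` to `contig_id`; if `NULL`
#'   the `"<contig>|p<k>"` naming convention is used.
#' @param min_identity,min_coverage confirming-hit thresholds.
#' @return `data.table` with `contig_id` and `confirmed_hits` (contigs with
#'   no passing protein are absent; treat as 0).
#' @export
count_confirmed <- function(hits, proteins = NULL, min_identity = 80,
                            min_coverage = 0.90) {
  passing <- filter_confirming_hits(hits, min_identity, min_coverage, ids = TRUE)
  if (is.null(proteins)) {
    contig <- protein_to_contig(passing)
  } else {
    proteins <- as.data.table(proteins)
    contig <- proteins$contig_id[match(passing, proteins$protein_id)]
    if (anyNA(contig)) {
      stop("protein '", passing[is.na(contig)][1], "' missing from protein map",
           call. = FALSE)
    }
  }
  dt <- data.table(contig_id = contig)
  dt[, .(confirmed_hits = .N), by = contig_id]
}

#' Assign length tiers to contigs
#'
#' Tiers are inclusive at the 1500 and 5000 bp boundaries: a contig of
#' exactly 5000 bp belongs to the networking tier.
#'
#' @param length_bp integer vector of contig lengths.
#' @param report_bp,network_bp tier cutoffs (bp).
#' @return character vector: `"below_1500"`, `"ge_1500"` or `"ge_5000"`.
#' @export
assign_tiers <- function(length_bp, report_bp = 1500L, network_bp = 5000L) {
  check_pos(length_bp, "length_bp")
  ifelse(length_bp >= network_bp, "ge_5000",
         ifelse(length_bp >= report_bp, "ge_1500", "below_1500"))
}

#' Call bona fide viral contigs from detector quorum plus confirmation
#'
#' A contig is called viral when it is flagged by at least `min_detectors`
#' of the configured detectors AND at least `min_confirming` of its distinct
#' proteins have a confirming reference hit. Every contig must carry an
#' entry for every configured detector; a missing entry is an evidence
#' error, not a silent `FALSE`.
#'
#' @param contigs data.frame with `contig_id`, `library_id`, `length_bp`.
#' @param evidence long-format data.frame with `contig_id`, `detector`,
#'   `flag` (logical).
#' @param confirmed output of [count_confirmed()] (or a data.frame with
#'   `contig_id`, `confirmed_hits`).
#' @param min_detectors detector quorum (default 2).
#' @param min_confirming minimum confirming proteins (default 2; the
#'   stricter "more than two" reading is `min_confirming = 3`).
#' @param detectors character vector of configured detector names; defaults
#'   to all detectors present in `evidence`.
#' @return `contigs` as a `data.table` with added `n_detectors`,
#'   `confirmed_hits`, `verdict` (`"viral"`/`"non_viral"`) and `tier`.
#' @export
call_viral <- function(contigs, evidence, confirmed, min_detectors = 2L,
                       min_confirming = 2L, detectors = NULL) {
  contigs <- as.data.table(contigs)
  evidence <- as.data.table(evidence)
  if (is.null(detectors)) detectors <- sort(unique(evidence$detector))
  ev <- evidence[detector %in% detectors]
  counts <- ev[, .(n_entries = .N, n_detectors = sum(flag)), by = contig_id]
  out <- merge(contigs, counts, by = "contig_id", all.x = TRUE, sort = FALSE)
  bad <- out$contig_id[is.na(out$n_entries) | out$n_entries < length(detectors)]
  if (length(bad)) {
    stop("contig '", bad[1], "' lacks evidence for all configured detectors (",
         paste(detectors, collapse = ", "), ")", call. = FALSE)
  }
  out[, n_entries := NULL]
  conf <- as.data.table(confirmed)
  out <- merge(out, conf[, .(contig_id, confirmed_hits)], by = "contig_id",
               all.x = TRUE, sort = FALSE)
  out[is.na(confirmed_hits), confirmed_hits := 0L]
  out[, verdict := ifelse(n_detectors >= min_detectors &
                            confirmed_hits >= min_confirming,
                          "viral", "non_viral")]
  out[, tier := assign_tiers(length_bp)]
  log_stage("call_viral", nrow(contigs), sum(out$verdict == "viral"))
  out[]
}

#' Per-library length-tier counts for called contigs
#'
#' Reproduces the attrition columns of the per-fraction summary table:
#' assembled contigs, assembled >=5 kb, viral verdicts at any length, viral
#' >=1.5 kb and viral >=5 kb. The three viral columns form a nested chain.
#'
#' @param contigs output of [call_viral()] (needs `library_id`, `length_bp`,
#'   `verdict`).
#' @param report_bp,network_bp tier cutoffs in bp.
#' @return `data.table`, one row per library.
#' @export
apply_tiers <- function(contigs, report_bp = 1500L, network_bp = 5000L) {
  contigs <- as.data.table(contigs)
  contigs[, .(
    assembled = .N,
    assembled_5kb = sum(length_bp >= network_bp),
    viral = sum(verdict == "viral"),
    viral_1500 = sum(verdict == "viral" & length_bp >= report_bp),
    viral_5kb = sum(verdict == "viral" & length_bp >= network_bp)
  ), by = library_id][order(library_id)]
}
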