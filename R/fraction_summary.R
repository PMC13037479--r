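#' Per-fraction summary table of assembled and viral-assigned contigs
#'
#' One row per sorted library: assembled contigs, assembled >= 5 kb, viral
#' verdicts at any length, viral >= 1.5 kb, viral >= 5 kb, and the headline
#' percentage `100 * viral_5kb / assembled_5kb` rounded half-up to one
#' decimal (reported missing when no contig reaches 5 kb). "Viral" counts
#' all verdicts irrespective of length, so it can exceed the >= 1.5 kb
#' column.
#'
#' @param contigs output of [call_viral()] (`library_id`, `length_bp`,
#'   `verdict`).
#' @param report_bp,network_bp tier cutoffs in bp.
#' @return `data.table`, one row per library, with `viral_5kb_pct`.
#' @export
summarize_fractions <- function(contigs, report_bp = 1500L, network_bp = 5000L) {
  out <- apply_tiers(contigs, report_bp = report_bp, network_bp = network_bp)
  out[, viral_5kb_pct := ifelse(assembled_5kb > 0,
                                round_half_up(100 * viral_5kb / assembled_5kb, 1),
                                NA_real_)]
  out[]
}

#' Fraction of candidate viral contigs with multiple confirming hits
#'
#' Candidates are contigs with a viral verdict at or above the reporting
#' tier (>= 1.5 kb). Returns the percentage with at least `min_hits`
#' confirming reference hits, rounded half-up to the nearest integer (the
#' "two or more viral hits" headline statistic).
#'
#' @param contigs output of [call_viral()] with `confirmed_hits` populated.
#' @param min_hits minimum confirming hits (default 2).
#' @param min_len candidate length cutoff in bp (default 1500).
#' @return integer percentage, or `NA` when the candidate set is empty.
#' @export
multi_hit_fraction <- function(contigs, min_hits = 2L, min_len = 1500L) {
  contigs <- as.data.table(contigs)
  cand <- contigs[verdict == "viral" & length_bp >= min_len]
  if (nrow(cand) == 0) return(NA_real_)
  round_half_up(100 * mean(cand$confirmed_hits >= min_hits), 0)
}

#' Per-lineage composition percentages and the modal lineage
#'
#' Percentages are computed on the unrounded fractions and then rounded
#' half-up to integers, so they may not sum to 100; they are reported as-is.
#' The modal lineage is the argmax with lexicographic tie-breaking.
#'
#' @param assignments character vector of lineage labels, one per item (for
#'   example, one per predicted host).
#' @return list with `percents` (a `data.table` of `lineage`, `n`, `pct`)
#'   and `modal` (the modal lineage label).
#' @export
lineage_fraction <- function(assignments) {
  if (length(assignments) < 1) stop("need at least one assignment", call. = FALSE)
  dt <- data.table(lineage = as.character(assignments))
  out <- dt[, .(n = .N), by = lineage]
  out[, pct := round_half_up(100 * n / length(assignments), 0)]
  setorder(out, -n, lineage)
  list(percents = out[], modal = out$lineage[1])
}

#' Render a fraction summary as a markdown table
#'
#' Mirrors the published per-population column order.
#'
#' @param summary output of [summarize_fractions()].
#' @return character vector of markdown lines.
#' @export
format_summary_md <- function(summary) {
  s <- as.data.table(summary)
  header <- paste("| Population | Assembled contigs | Assembled 5 Kb |",
                  "Viral assigned | Viral assigned 1.5 Kb | Viral assigned 5 Kb |",
                  "Viral assigned 5 Kb, % |")
  sep <- paste0("|", paste(rep("---|", 7), collapse = ""))
  rows <- s[, sprintf("| %s | %d | %d | %d | %d | %d | %s |", library_id,
                      assembled, assembled_5kb, viral, viral_1500, viral_5kb,
                      ifelse(is.na(viral_5kb_pct), "-",
                             formatC(viral_5kb_pct, format = "f", digits = 1)))]
  c(header, sep, rows)
}
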