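#' Read a FASTA file into a named character vector
#'
#' Accepts wrapped and single-line dialects and CRLF line endings. An empty
#' file yields an empty vector; a duplicated record id is a format error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are full header lines).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate FASTA id '%s' in %s", dup[[1]], path), call. = FALSE)
  }
  setNames(as.character(set), ids)
}

#' Write sequences to FASTA, wrapped at 80 columns
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("all records must be named", call. = FALSE)
  }
  if (anyDuplicated(names(records))) {
    stop("duplicate FASTA id '", names(records)[duplicated(names(records))][1],
         "'", call. = FALSE)
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

hit_columns <- c(
  "query_id", "subject_id", "pct_identity", "aln_length", "mismatches",
  "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read a 12-column tabular alignment (BLAST outfmt 6) hit table
#'
#' Column order is the tabular convention: query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' e-value, bit score. A header line is auto-detected (non-numeric third
#' column). Coordinates stay 1-based inclusive as in the format.
#'
#' @param path path to the tab-separated hit table.
#' @param query_lengths optional named vector or two-column data.frame
#'   (`query_id`, `query_length`) used to attach query lengths for coverage
#'   computation.
#' @return a `data.table` with the 12 canonical columns (plus `query_length`
#'   when provided).
#' @export
read_hits <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- as.data.table(setNames(
    c(list(character(0), character(0)), rep(list(numeric(0)), 10)), hit_columns))
  if (file.size(path) == 0) return(attach_query_lengths(empty, query_lengths))
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf)) {
    bad <- which(nf != 12L)
    if (length(bad)) {
      stop(sprintf("expected 12 tab-separated columns, found %d at line %d of %s",
                   nf[bad[1]], bad[1], path), call. = FALSE)
    }
  }
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- length(first) == 12L && is.na(suppressWarnings(as.numeric(first[3])))
  hits <- fread(path, sep = "\t", header = FALSE, skip = if (has_header) 1L else 0L,
                colClasses = list(character = 1:2, numeric = c(3, 11, 12),
                                  integer = 4:10))
  if (nrow(hits) == 0 && ncol(hits) == 0) hits <- data.table::copy(empty)
  data.table::setnames(hits, hit_columns)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("pct_identity outside [0, 100] in ", path, call. = FALSE)
  }
  attach_query_lengths(hits, query_lengths)
}

attach_query_lengths <- function(hits, query_lengths) {
  if (is.null(query_lengths)) return(hits[])
  if (is.data.frame(query_lengths)) {
    ql <- setNames(as.integer(query_lengths[[2]]), query_lengths[[1]])
  } else {
    ql <- setNames(as.integer(query_lengths), names(query_lengths))
  }
  hits[, query_length := as.integer(ql[query_id])]
  hits[]
}

#' Write a hit table in 12-column tabular format (no header)
#'
#' @param hits data.frame with the canonical hit columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  fwrite(as.data.table(hits)[, hit_columns, with = FALSE], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a headered TSV table
#'
#' Thin wrappers used for contig metadata, evidence, cluster and summary
#' tables so every stage round-trips through plain text.
#'
#' @param path file path.
#' @return `read_tsv()` returns a `data.table`; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) fread(path, sep = "\t", header = TRUE)

#' @param x data.frame to write.
#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every threshold the pipeline applies, defaulting to the published
#' screening values: confirming protein hits at >=80 percent identity and
#' >=90 percent query coverage with >=2 confirming proteins; detector quorum
#' of 2; reporting tier at 1500 bp and networking tier at 5000 bp; gp23
#' marker screen at bit score > 50 and e-value < 1e-10; host linkage at >=80
#' percent shared proteins, >=60 percent amino-acid identity, >=95 percent
#' coverage. MCL, bootstrap and RNG settings travel in the same object.
#'
#' @param min_identity minimum percent identity for a confirming hit.
#' @param min_coverage minimum query coverage (fraction) for a confirming hit.
#' @param min_confirming_proteins confirming distinct proteins required to
#'   corroborate a viral contig.
#' @param min_detectors detector quorum for a viral verdict.
#' @param contig_min_report_bp reporting length tier (bp).
#' @param contig_min_network_bp networking length tier (bp).
#' @param gp23_min_bitscore,gp23_max_evalue gp23 marker screen thresholds
#'   (strict inequalities).
#' @param host_min_shared,host_min_aai,host_min_cov host-linkage thresholds
#'   (inclusive, as fractions).
#' @param inflation,max_iter,tol,prune_floor MCL parameters.
#' @param min_weight minimum `-log10(p)` edge weight kept in the genome network.
#' @param n_boot,ci_level bootstrap replicate count and interval level.
#' @param seed integer seed for all stochastic steps.
#' @return a validated `viroturn_config` list.
#' @export
run_config <- function(min_identity = 80, min_coverage = 0.90,
                       min_confirming_proteins = 2L, min_detectors = 2L,
                       contig_min_report_bp = 1500L, contig_min_network_bp = 5000L,
                       gp23_min_bitscore = 50, gp23_max_evalue = 1e-10,
                       host_min_shared = 0.80, host_min_aai = 0.60,
                       host_min_cov = 0.95,
                       inflation = 2.0, max_iter = 100L, tol = 1e-6,
                       prune_floor = 1e-6, min_weight = 1,
                       n_boot = 1000L, ci_level = 0.95, seed = 1L) {
  cfg <- list(
    min_identity = min_identity, min_coverage = min_coverage,
    min_confirming_proteins = as.integer(min_confirming_proteins),
    min_detectors = as.integer(min_detectors),
    contig_min_report_bp = as.integer(contig_min_report_bp),
    contig_min_network_bp = as.integer(contig_min_network_bp),
    gp23_min_bitscore = gp23_min_bitscore, gp23_max_evalue = gp23_max_evalue,
    host_min_shared = host_min_shared, host_min_aai = host_min_aai,
    host_min_cov = host_min_cov,
    inflation = inflation, max_iter = as.integer(max_iter), tol = tol,
    prune_floor = prune_floor, min_weight = min_weight,
    n_boot = as.integer(n_boot), ci_level = ci_level, seed = as.integer(seed)
  )
  if (cfg$min_identity < 0 || cfg$min_identity > 100)
    stop_field("min_identity", "must lie in [0, 100]")
  check_prob(cfg$min_coverage, "min_coverage")
  check_prob(cfg$host_min_shared, "host_min_shared")
  check_prob(cfg$host_min_aai, "host_min_aai")
  check_prob(cfg$host_min_cov, "host_min_cov")
  check_prob(cfg$ci_level, "ci_level")
  if (cfg$min_confirming_proteins < 0) stop_field("min_confirming_proteins", "must be >= 0")
  if (cfg$min_detectors < 1) stop_field("min_detectors", "must be >= 1")
  check_pos(cfg$contig_min_report_bp, "contig_min_report_bp")
  check_pos(cfg$contig_min_network_bp, "contig_min_network_bp")
  if (cfg$inflation <= 1) stop_field("inflation", "must be > 1")
  check_pos(cfg$max_iter, "max_iter")
  check_pos(cfg$tol, "tol")
  if (cfg$prune_floor < 0) stop_field("prune_floor", "must be >= 0")
  if (cfg$gp23_max_evalue < 0) stop_field("gp23_max_evalue", "must be >= 0")
  structure(cfg, class = "viroturn_config")
}

#' Read / write run configuration as JSON
#'
#' Unknown keys are rejected loudly rather than silently dropped; omitted
#' keys keep their defaults.
#'
#' @param path JSON config file path.
#' @return `read_config()` returns a `viroturn_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @param config a `viroturn_config` object.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
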