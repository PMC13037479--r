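AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specify a virus or host lineage of the synthetic community
#'
#' A lineage is the ground-truth unit of the simulator: it owns a genome
#' length, a protein repertoire, a within-lineage divergence level and —
#' depending on its kind — either a turnover probability (the chance that a
#' free virion of the lineage was newly produced, i.e. BONCAT-positive,
#' during the incubation) or a translational-activity probability.
#'
#' @param lineage_id identifier.
#' @param kind `"viral"` or `"host"`.
#' @param relative_abundance fraction in \[0, 1\]; abundances must sum to 1
#'   within each kind across the community.
#' @param turnover_theta viral lineages only: probability in \[0, 1\] that a
#'   free virion is newly produced (BONCAT-positive).
#' @param activity_prob host lineages only: probability a cell is
#'   translationally active.
#' @param genome_length_bp positive genome length.
#' @param n_proteins repertoire size (>= 1).
#' @param protein_divergence per-site substitution probability among
#'   within-lineage genomes.
#' @param infection_link optional host `lineage_id` infected by this virus.
#' @return a validated `lineage_spec` list.
#' @export
lineage_spec <- function(lineage_id, kind = c("viral", "host"),
                         relative_abundance, turnover_theta = NA_real_,
                         activity_prob = NA_real_, genome_length_bp = 40000L,
                         n_proteins = 25L, protein_divergence = 0.05,
                         infection_link = NA_character_) {
  kind <- match.arg(kind)
  check_prob(relative_abundance, "relative_abundance")
  if (kind == "viral") {
    check_prob(turnover_theta, "turnover_theta")
  } else {
    check_prob(activity_prob, "activity_prob")
  }
  check_pos(genome_length_bp, "genome_length_bp")
  if (n_proteins < 1) stop_field("n_proteins", "must be >= 1")
  check_prob(protein_divergence, "protein_divergence")
  structure(list(
    lineage_id = as.character(lineage_id), kind = kind,
    relative_abundance = relative_abundance,
    turnover_theta = turnover_theta, activity_prob = activity_prob,
    genome_length_bp = as.integer(genome_length_bp),
    n_proteins = as.integer(n_proteins),
    protein_divergence = protein_divergence,
    infection_link = infection_link
  ), class = "lineage_spec")
}

#' Specify one FACS-sorted library (pool)
#'
#' The BONCAT state follows from the fraction: viral progeny and active
#' cells are the BONCAT-positive sorts.
#'
#' @param library_id identifier.
#' @param fraction one of `"viral_progeny"`, `"pre_existing_viruses"`,
#'   `"active_cells"`, `"inactive_cells"`.
#' @param sorted_depth positive count of sorted particles/cells.
#' @param site sampling-site label (ratios pool per site by default).
#' @param click_minutes click-reaction duration label.
#' @return a validated `sorted_library` list.
#' @export
sorted_library <- function(library_id, fraction = c(
                             "viral_progeny", "pre_existing_viruses",
                             "active_cells", "inactive_cells"),
                           sorted_depth, site = "site1", click_minutes = 30) {
  fraction <- match.arg(fraction)
  check_pos(sorted_depth, "sorted_depth")
  check_pos(click_minutes, "click_minutes")
  structure(list(
    library_id = as.character(library_id), site = as.character(site),
    fraction = fraction,
    boncat_positive = fraction %in% c("viral_progeny", "active_cells"),
    sorted_depth = as.integer(sorted_depth), click_minutes = click_minutes
  ), class = "sorted_library")
}

#' Assemble a synthetic sorted-community specification
#'
#' Bundles the lineage ground truth, the sorted libraries and the global
#' simulation parameters: lognormal contig lengths, per-detector
#' sensitivity/false-positive rates, gamma-distributed per-particle
#' amplification weights (whole-genome amplification bias stand-in;
#' `shape -> Inf` recovers unbiased sampling), the per-particle contig yield
#' (one contig per sorted particle, thinned to `contig_yield * depth`
#' contigs per library), and the fraction of cell-sort contigs that are
#' viral (infections seen inside sorted cells).
#'
#' @param lineages list of [lineage_spec()] objects.
#' @param libraries list of [sorted_library()] objects.
#' @param length_log_mean,length_log_sd lognormal contig-length parameters
#'   (log-bp scale).
#' @param detector_sensitivity,detector_fpr per-detector true/false positive
#'   probabilities.
#' @param amplification_dispersion gamma shape for per-particle
#'   amplification weight (> 0).
#' @param contig_yield contigs recovered per sorted particle in (0, 1].
#' @param contamination_rate probability a viral-fraction particle is
#'   cellular debris (uncalibrated; default 0).
#' @param active_cell_viral_frac,inactive_cell_viral_frac fraction of
#'   cell-sort contigs that are viral.
#' @param detectors names of the evidence channels.
#' @param n_variants within-lineage variant genomes per lineage.
#' @param seed integer seed; the simulator uses one RNG stream seeded once.
#' @return a validated `community_spec` list.
#' @export
community_spec <- function(lineages, libraries,
                           length_log_mean = log(8000), length_log_sd = 0.7,
                           detector_sensitivity = 0.95, detector_fpr = 0.02,
                           amplification_dispersion = 5,
                           contig_yield = 0.015, contamination_rate = 0,
                           active_cell_viral_frac = 0.5,
                           inactive_cell_viral_frac = 0.02,
                           detectors = c("virsorter", "genomad", "checkv"),
                           n_variants = 3L, seed = 1L) {
  stopifnot(length(lineages) >= 1, length(libraries) >= 1)
  for (ln in lineages) {
    if (!inherits(ln, "lineage_spec")) stop("lineages must be lineage_spec objects", call. = FALSE)
  }
  for (lb in libraries) {
    if (!inherits(lb, "sorted_library")) stop("libraries must be sorted_library objects", call. = FALSE)
  }
  ids <- vapply(lineages, `[[`, character(1), "lineage_id")
  if (anyDuplicated(ids)) stop_field("lineage_id", "must be unique")
  for (k in c("viral", "host")) {
    ab <- vapply(lineages, function(l) {
      if (l$kind == k) l$relative_abundance else NA_real_
    }, numeric(1))
    ab <- ab[!is.na(ab)]
    if (length(ab) && abs(sum(ab) - 1) > 1e-9) {
      stop_field("relative_abundance",
                 sprintf("%s abundances must sum to 1 (got %.6f)", k, sum(ab)))
    }
  }
  check_prob(detector_sensitivity, "detector_sensitivity")
  check_prob(detector_fpr, "detector_fpr")
  check_pos(amplification_dispersion, "amplification_dispersion")
  check_prob(contig_yield, "contig_yield")
  check_pos(contig_yield, "contig_yield")
  check_prob(contamination_rate, "contamination_rate")
  check_prob(active_cell_viral_frac, "active_cell_viral_frac")
  check_prob(inactive_cell_viral_frac, "inactive_cell_viral_frac")
  if (!is.finite(length_log_mean) || length_log_sd < 0) {
    stop_field("length_log_mean/length_log_sd", "must yield positive lengths")
  }
  structure(list(
    lineages = lineages, libraries = libraries,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    detector_sensitivity = detector_sensitivity, detector_fpr = detector_fpr,
    amplification_dispersion = amplification_dispersion,
    contig_yield = contig_yield, contamination_rate = contamination_rate,
    active_cell_viral_frac = active_cell_viral_frac,
    inactive_cell_viral_frac = inactive_cell_viral_frac,
    detectors = detectors, n_variants = as.integer(n_variants),
    seed = as.integer(seed)
  ), class = "community_spec")
}

#' Default synthetic world: a two-fraction-pair coastal sort
#'
#' Three viral lineages with contrasted turnover (theta 0.9 / 0.5 / 0.1) and
#' two host lineages with contrasted activity, sorted into the four
#' canonical fractions at the depths of the deep-sorted experiment: 100,000
#' progeny VLPs, 50,000 pre-existing VLPs, 25,000 active and 25,000
#' non-active cells.
#'
#' @param seed integer seed.
#' @param theta turnover probabilities of the three viral lineages.
#' @param ... further arguments passed to [community_spec()].
#' @return a `community_spec`.
#' @export
default_community_spec <- function(seed = 1L, theta = c(0.9, 0.5, 0.1), ...) {
  nv <- length(theta)
  viral <- lapply(seq_len(nv), function(i) {
    lineage_spec(paste0("v", i), "viral", relative_abundance = 1 / nv,
                 turnover_theta = theta[i], genome_length_bp = 40000L,
                 n_proteins = 25L, protein_divergence = 0.05,
                 infection_link = paste0("h", 1 + (i - 1) %% 2))
  })
  hosts <- list(
    lineage_spec("h1", "host", relative_abundance = 0.5, activity_prob = 0.8,
                 genome_length_bp = 2000000L, n_proteins = 50L,
                 protein_divergence = 0.02),
    lineage_spec("h2", "host", relative_abundance = 0.5, activity_prob = 0.1,
                 genome_length_bp = 2000000L, n_proteins = 50L,
                 protein_divergence = 0.02)
  )
  libs <- list(
    sorted_library("pos_vlp", "viral_progeny", 100000L, site = "pacific"),
    sorted_library("neg_vlp", "pre_existing_viruses", 50000L, site = "pacific"),
    sorted_library("act_cell", "active_cells", 25000L, site = "pacific"),
    sorted_library("inact_cell", "inactive_cells", 25000L, site = "pacific")
  )
  community_spec(c(viral, hosts), libs, seed = seed, ...)
}

# substitute each position independently with probability d (to a different
# residue, so observed divergence equals d with no back-substitution)
mutate_seq <- function(chars, d) {
  if (d <= 0) return(chars)
  hit <- runif(length(chars)) < d
  n <- sum(hit)
  if (n) {
    repl <- AA20[ceiling(runif(n) * 19)]
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- AA20[ceiling(runif(sum(same)) * 20)]
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  chars
}

#' Generate lineage reference genomes with protein repertoires
#'
#' Draws, for every lineage, `n_proteins` ancestral protein sequences
#' (lognormal lengths around 250 aa) and `n_variants` within-lineage variant
#' genomes whose proteins diverge from the ancestor at
#' `protein_divergence` per site.
#'
#' @param spec a [community_spec()].
#' @param seed optional seed; when `NULL` (the default inside
#'   [simulate_community()]) the current RNG stream is consumed.
#' @return named list per lineage: `proteins` (ancestral, named
#'   `"<lineage>_ref_p<k>"`), `protein_lengths`, and `variants` (list of
#'   character vectors).
#' @export
generate_lineages <- function(spec, seed = NULL) {
  if (!inherits(spec, "community_spec")) stop("spec must be a community_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(spec$lineages, function(ln) {
    lens <- pmax(50L, as.integer(round(rlnorm(ln$n_proteins, log(250), 0.3))))
    anc <- lapply(lens, function(L) AA20[ceiling(runif(L) * 20)])
    names(anc) <- sprintf("%s_ref_p%d", ln$lineage_id, seq_along(anc))
    variants <- lapply(seq_len(spec$n_variants), function(v) {
      vs <- vapply(anc, function(ch) paste(mutate_seq(ch, ln$protein_divergence),
                                           collapse = ""), character(1))
      names(vs) <- sprintf("%s_var%d_p%d", ln$lineage_id, v, seq_along(vs))
      vs
    })
    list(lineage_id = ln$lineage_id,
         proteins = vapply(anc, paste, character(1), collapse = ""),
         protein_lengths = setNames(lens, names(anc)),
         variants = variants)
  })
  names(out) <- vapply(spec$lineages, `[[`, character(1), "lineage_id")
  out
}

# per-lineage sampling weights for one sorted fraction
fraction_weights <- function(spec, fraction) {
  ids <- vapply(spec$lineages, `[[`, character(1), "lineage_id")
  kind <- vapply(spec$lineages, `[[`, character(1), "kind")
  ab <- vapply(spec$lineages, `[[`, numeric(1), "relative_abundance")
  theta <- vapply(spec$lineages, `[[`, numeric(1), "turnover_theta")
  act <- vapply(spec$lineages, `[[`, numeric(1), "activity_prob")
  w <- setNames(numeric(length(ids)), ids)
  norm <- function(x) if (sum(x) > 0) x / sum(x) else x
  vir <- kind == "viral"; hst <- kind == "host"
  if (fraction == "viral_progeny") {
    w[vir] <- norm(ab[vir] * theta[vir]) * (1 - spec$contamination_rate)
    w[hst] <- norm(ab[hst]) * spec$contamination_rate
  } else if (fraction == "pre_existing_viruses") {
    w[vir] <- norm(ab[vir] * (1 - theta[vir])) * (1 - spec$contamination_rate)
    w[hst] <- norm(ab[hst]) * spec$contamination_rate
  } else {
    vfrac <- if (fraction == "active_cells") spec$active_cell_viral_frac else
      spec$inactive_cell_viral_frac
    aw <- if (fraction == "active_cells") act[hst] else (1 - act[hst])
    w[hst] <- norm(ab[hst] * aw) * (1 - vfrac)
    w[vir] <- norm(ab[vir]) * vfrac
  }
  w
}

#' Simulate FACS sorting of every library
#'
#' For a viral lineage with abundance `a` and turnover `theta`, a sorted
#' progeny-fraction virion belongs to it with probability proportional to
#' `a * theta`, and a pre-existing-fraction virion with probability
#' proportional to `a * (1 - theta)`; cell fractions weight host lineages by
#' abundance times (in)activity, with a configurable viral admixture
#' standing in for infections inside sorted cells. Counts are multinomial
#' and each library's total equals its sorted depth exactly.
#'
#' @param spec a [community_spec()].
#' @param seed optional seed (see [generate_lineages()]).
#' @return `data.table` with `library_id`, `lineage_id`, `count`.
#' @export
simulate_sorting <- function(spec, seed = NULL) {
  if (!inherits(spec, "community_spec")) stop("spec must be a community_spec", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(spec$libraries, function(lb) {
    w <- fraction_weights(spec, lb$fraction)
    if (sum(w) <= 0) {
      stop(sprintf(
        "degenerate community: no abundance mass for fraction '%s' (library '%s')",
        lb$fraction, lb$library_id), call. = FALSE)
    }
    cnt <- as.integer(rmultinom(1, lb$sorted_depth, w))
    data.table(library_id = lb$library_id, lineage_id = names(w), count = cnt)
  })
  rbindlist(rows)[]
}

#' Fragment sorted particles into annotated contigs with detector evidence
#'
#' One contig per sorted particle (no co-assembly), thinned to
#' `contig_yield * sorted_depth` contigs per library with per-particle
#' gamma amplification weights (shape `amplification_dispersion`). Contig
#' lengths are lognormal, clamped to the lineage genome length; each contig
#' carries `max(2, round(n_proteins * length / genome_length))` proteins.
#' Detector flags are Bernoulli with `detector_sensitivity` on truly viral
#' contigs and `detector_fpr` otherwise, independently per detector. Hit
#' rows record each viral contig protein against its lineage reference
#' protein with identity consistent with `protein_divergence` and full
#' query coverage.
#'
#' @param counts output of [simulate_sorting()].
#' @param spec the [community_spec()].
#' @param lineages output of [generate_lineages()].
#' @param outdir optional directory; when given, contig and protein FASTA
#'   plus metadata/evidence/hits/protein-length TSVs are written there
#'   (sequence realisation happens after all tables are drawn, so tables
#'   are identical whether or not files are emitted).
#' @param seed optional seed (see [generate_lineages()]).
#' @return list with `contigs`, `evidence`, `hits` (12 tabular columns plus
#'   `query_length`), `proteins`, and `files` (paths, when written).
#' @export
fragment_and_annotate <- function(counts, spec, lineages, outdir = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.data.table(counts)
  lin_by_id <- setNames(spec$lineages,
                        vapply(spec$lineages, `[[`, character(1), "lineage_id"))
  lib_by_id <- setNames(spec$libraries,
                        vapply(spec$libraries, `[[`, character(1), "library_id"))

  contig_rows <- list(); protein_rows <- list(); hit_rows <- list()
  for (lib_id in vapply(spec$libraries, `[[`, character(1), "library_id")) {
    lb <- lib_by_id[[lib_id]]
    cc <- counts[library_id == lib_id]
    depth <- lb$sorted_depth
    m <- max(1L, as.integer(round(spec$contig_yield * depth)))
    particle_lineage <- rep(cc$lineage_id, cc$count)
    wamp <- rgamma(depth, shape = spec$amplification_dispersion,
                   rate = spec$amplification_dispersion)
    idx <- if (m < depth) sample.int(depth, m, prob = wamp) else seq_len(depth)
    lng <- particle_lineage[idx]
    glen <- vapply(lin_by_id[lng], `[[`, integer(1), "genome_length_bp")
    len <- as.integer(round(rlnorm(length(idx), spec$length_log_mean,
                                   spec$length_log_sd)))
    len <- pmin(pmax(len, 200L), glen)
    kind <- vapply(lin_by_id[lng], `[[`, character(1), "kind")
    ids <- sprintf("%s_c%04d", lib_id, seq_along(idx))
    contig_rows[[lib_id]] <- data.table(
      library_id = lib_id, contig_id = ids, lineage_id = lng,
      length_bp = len, true_viral = kind == "viral",
      true_boncat = lb$boncat_positive
    )
    nprot_rep <- vapply(lin_by_id[lng], `[[`, integer(1), "n_proteins")
    np <- pmin(nprot_rep, pmax(2L, as.integer(round(nprot_rep * len / glen))))
    div <- vapply(lin_by_id[lng], `[[`, numeric(1), "protein_divergence")
    ctg <- rep(ids, np)
    lng_p <- rep(lng, np)
    div_p <- rep(div, np)
    viral_p <- rep(kind == "viral", np)
    pnum <- sequence(np)
    # each contig protein derives from a random reference of its lineage
    ref_idx <- unlist(lapply(seq_along(ids), function(i) {
      sample.int(nprot_rep[i], np[i], replace = FALSE)
    }))
    ref_id <- sprintf("%s_ref_p%d", lng_p, ref_idx)
    plen <- mapply(function(l, r) lineages[[l]]$protein_lengths[[r]],
                   lng_p, ref_idx)
    pid <- sprintf("%s|p%d", ctg, pnum)
    protein_rows[[lib_id]] <- data.table(
      protein_id = pid, contig_id = ctg, lineage_id = lng_p,
      ref_id = ref_id, ref_idx = ref_idx, length = as.integer(plen),
      divergence = div_p, viral = viral_p
    )
    vsel <- viral_p
    if (any(vsel)) {
      nmut <- rbinom(sum(vsel), plen[vsel], div_p[vsel])
      identity <- 100 * (1 - nmut / plen[vsel])
      hit_rows[[lib_id]] <- data.table(
        query_id = pid[vsel], subject_id = ref_id[vsel],
        pct_identity = identity, aln_length = as.integer(plen[vsel]),
        mismatches = as.integer(nmut), gap_opens = 0L,
        qstart = 1L, qend = as.integer(plen[vsel]),
        sstart = 1L, send = as.integer(plen[vsel]),
        evalue = 10^-pmin(180, 0.3 * plen[vsel]),
        bitscore = round(2 * plen[vsel] * (1 - nmut / plen[vsel]), 1),
        query_length = as.integer(plen[vsel])
      )
    }
  }
  contigs <- rbindlist(contig_rows)
  proteins <- rbindlist(protein_rows)
  hits <- if (length(hit_rows)) rbindlist(hit_rows) else NULL
  if (is.null(hits)) {
    hits <- as.data.table(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 11)),
      c(hit_columns, "query_length")))
  }

  # detector evidence, independent per detector
  nd <- length(spec$detectors)
  p_flag <- ifelse(rep(contigs$true_viral, each = nd),
                   spec$detector_sensitivity, spec$detector_fpr)
  flags <- runif(nrow(contigs) * nd) < p_flag
  evidence <- data.table(
    contig_id = rep(contigs$contig_id, each = nd),
    detector = rep(spec$detectors, times = nrow(contigs)),
    flag = flags,
    score = round(ifelse(flags, 0.5 + 0.5 * runif(length(flags)),
                         0.5 * runif(length(flags))), 4)
  )

  files <- NULL
  if (!is.null(outdir)) {
    files <- write_simulation(contigs, evidence, hits, proteins, lineages, outdir)
  }
  list(contigs = contigs[], evidence = evidence[], hits = hits[],
       proteins = proteins[], files = files)
}

# sequence realisation + file emission; runs after all tables are drawn so
# the tables do not depend on whether files are requested
write_simulation <- function(contigs, evidence, hits, proteins, lineages, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  dna <- vapply(contigs$length_bp, function(L) {
    paste(c("A", "C", "G", "T")[ceiling(runif(L) * 4)], collapse = "")
  }, character(1))
  names(dna) <- contigs$contig_id
  pseq <- vapply(seq_len(nrow(proteins)), function(i) {
    anc <- lineages[[proteins$lineage_id[i]]]$proteins[[proteins$ref_id[i]]]
    paste(mutate_seq(strsplit(anc, "", fixed = TRUE)[[1]],
                     proteins$divergence[i]), collapse = "")
  }, character(1))
  names(pseq) <- proteins$protein_id
  paths <- list(
    contigs_fasta = file.path(outdir, "contigs.fasta"),
    proteins_fasta = file.path(outdir, "proteins.fasta"),
    metadata = file.path(outdir, "metadata.tsv"),
    evidence = file.path(outdir, "evidence.tsv"),
    hits = file.path(outdir, "hits.tsv"),
    protein_lengths = file.path(outdir, "protein_lengths.tsv")
  )
  write_fasta(dna, paths$contigs_fasta)
  write_fasta(pseq, paths$proteins_fasta)
  write_tsv(contigs[, .(library_id, contig_id, lineage_id, length_bp,
                        true_viral, true_boncat)], paths$metadata)
  write_tsv(evidence, paths$evidence)
  write_hits(hits, paths$hits)
  write_tsv(proteins[, .(protein_id, length)], paths$protein_lengths)
  paths
}

#' Run the whole simulator under one seeded RNG stream
#'
#' Seeds once from `spec$seed` and consumes the stream in documented order:
#' lineage generation, sorting, contig/evidence/hit tables, then (only when
#' `outdir` is given) sequence realisation. Re-running with the same spec is
#' byte-identical.
#'
#' @param spec a [community_spec()].
#' @param outdir optional output directory for FASTA/TSV emission.
#' @return list with `spec`, `lineages`, `counts` and the tables of
#'   [fragment_and_annotate()].
#' @export
simulate_community <- function(spec, outdir = NULL) {
  set.seed(spec$seed)
  lineages <- generate_lineages(spec)
  counts <- simulate_sorting(spec)
  ann <- fragment_and_annotate(counts, spec, lineages, outdir = outdir)
  c(list(spec = spec, lineages = lineages, counts = counts), ann)
}
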