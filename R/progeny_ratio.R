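#' Depth-normalised viral progeny ratio
#'
#' The turnover statistic of sorted-virome comparisons: the proportion of newly produced
#' (BONCAT-positive) virions relative to all virions in a cluster, after
#' normalising each library's member count by the number of particles sorted
#' into it. With `n_pos` members from the progeny library (sorted depth
#' `D_pos`) and `n_neg` from the pre-existing library (depth `D_neg`),
#' \deqn{R = \frac{n_{pos}/D_{pos}}{n_{pos}/D_{pos} + n_{neg}/D_{neg}}.}
#' Equal depths reduce to the raw proportion `n_pos / (n_pos + n_neg)`, and
#' the ratio is invariant under scaling both depths by the same factor.
#'
#' @param n_pos,n_neg member counts from BONCAT-positive and -negative viral
#'   libraries (vectorised).
#' @param D_pos,D_neg sorted particle depths of those libraries (> 0).
#' @return numeric ratio in \[0, 1\]; `NA` where both counts are zero (an
#'   undefined ratio is reported as missing, not as 0).
#' @export
#' @examples
#' progeny_ratio(15, 2, 100000, 50000)   # 0.7894737 -> 78.95%
progeny_ratio <- function(n_pos, n_neg, D_pos, D_neg) {
  if (any(D_pos <= 0) || any(D_neg <= 0)) {
    stop("sorted depths must be > 0", call. = FALSE)
  }
  if (any(n_pos < 0) || any(n_neg < 0)) {
    stop("member counts must be >= 0", call. = FALSE)
  }
  rate_pos <- n_pos / D_pos
  rate_neg <- n_neg / D_neg
  out <- rate_pos / (rate_pos + rate_neg)
  out[n_pos + n_neg == 0] <- NA_real_
  out
}

#' Progeny ratio as a printed percentage
#'
#' @inheritParams progeny_ratio
#' @param digits decimals in the printed percentage (default 2).
#' @return percentage rounded half-up, e.g. 78.95.
#' @export
progeny_ratio_pct <- function(n_pos, n_neg, D_pos, D_neg, digits = 2) {
  round_half_up(100 * progeny_ratio(n_pos, n_neg, D_pos, D_neg), digits)
}

#' Enumerate integer splits reproducing a printed cluster percentage
#'
#' For a cluster of printed size `n_total`, tries every split
#' `(k, n_total - k)` for `k = 0..n_total` and returns those whose
#' depth-normalised ratio, printed as a percentage at `digits` decimals,
#' equals `target_pct`. Used as the independent oracle that pins the member
#' splits behind printed cluster ratios (a unique match identifies the
#' split).
#'
#' @param n_total cluster size.
#' @param D_pos,D_neg sorted depths.
#' @param target_pct printed percentage to reproduce.
#' @param digits printed precision (default 2).
#' @return integer vector of matching `n_pos` values (possibly empty).
#' @export
enumerate_ratio_splits <- function(n_total, D_pos, D_neg, target_pct, digits = 2) {
  k <- 0:n_total
  pct <- progeny_ratio_pct(k, n_total - k, D_pos, D_neg, digits)
  k[!is.na(pct) & pct == target_pct]
}

#' Bootstrap percentile interval for a progeny ratio
#'
#' Nonparametric bootstrap: the `n_pos + n_neg` member labels are resampled
#' with replacement (equivalently, the bootstrap positive count is binomial
#' with the observed label proportion), the depth-normalised ratio is
#' recomputed for each replicate, and the percentile interval is returned.
#'
#' @inheritParams progeny_ratio
#' @param n_boot bootstrap replicates (default 1000; fewer than 100 draws a
#'   configuration warning).
#' @param ci_level interval level (default 0.95).
#' @param seed optional integer seed; the global RNG state is restored on
#'   exit.
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(n_pos, n_neg, D_pos, D_neg, n_boot = 1000L,
                         ci_level = 0.95, seed = NULL) {
  n <- n_pos + n_neg
  if (n < 1) stop("n_pos + n_neg must be >= 1", call. = FALSE)
  if (n_boot < 100) {
    warning("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  bpos <- rbinom(n_boot, n, n_pos / n)
  ratios <- progeny_ratio(bpos, n - bpos, D_pos, D_neg)
  alpha <- (1 - ci_level) / 2
  q <- quantile(ratios, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

#' Per-cluster depth-normalised progeny ratios
#'
#' Only members from the two viral sorted fractions enter the ratio:
#' `viral_progeny` libraries contribute to `n_pos`, `pre_existing_viruses`
#' libraries to `n_neg`; members from cell fractions (and reference genomes)
#' are excluded. When several libraries of the same sign are pooled, the
#' pooled rate is `sum(n_i) / sum(D_i)` over that sign. By default pooling
#' is per site and only sites that sorted both viral fractions enter; with
#' `pool_sites = TRUE` all sites are pooled into one pair of rates. Clusters
#' with no usable members are reported with a missing ratio and a reason
#' code rather than dropped.
#'
#' @param clusters output of [cluster_genomes()] (`cluster_id`, `member`,
#'   `is_reference`).
#' @param contig_meta data.frame mapping `contig_id` to `library_id`.
#' @param libraries data.frame with `library_id`, `site`, `fraction`,
#'   `sorted_depth` (fractions: `viral_progeny`, `pre_existing_viruses`,
#'   `active_cells`, `inactive_cells`).
#' @param pool_sites pool across sites irrespective of completeness
#'   (default `FALSE`).
#' @param n_boot,ci_level,seed bootstrap settings ([bootstrap_ci()]); per
#'   cluster seeds are derived from `seed`.
#' @return `data.table` with `cluster_id`, `n_pos`, `n_neg`, `D_pos`,
#'   `D_neg`, `n_total`, `ratio`, `ratio_pct`, `ci_low`, `ci_high`,
#'   `reason` (`"ok"`, `"no viral-fraction members"`,
#'   `"no negative viral library"`).
#' @export
cluster_ratios <- function(clusters, contig_meta, libraries, pool_sites = FALSE,
                           n_boot = 1000L, ci_level = 0.95, seed = 1L) {
  libraries <- as.data.table(libraries)
  counts <- count_cluster_libraries(clusters, contig_meta)
  unknown <- setdiff(counts$library_id, libraries$library_id)
  if (length(unknown)) {
    stop("cluster member(s) from library '", unknown[1],
         "' absent from the library table", call. = FALSE)
  }
  counts <- merge(counts, libraries[, .(library_id, site, fraction, sorted_depth)],
                  by = "library_id")
  viral_fracs <- c("viral_progeny", "pre_existing_viruses")
  # sites with both viral fractions sorted; others cannot yield a ratio
  site_frac <- unique(libraries[fraction %in% viral_fracs, .(site, fraction)])
  complete_sites <- site_frac[, .N, by = site][N == 2L, site]
  usable <- counts[fraction %in% viral_fracs]
  if (!pool_sites) usable <- usable[site %in% complete_sites]
  lib_pool <- libraries[fraction %in% viral_fracs]
  if (!pool_sites) lib_pool <- lib_pool[site %in% complete_sites]
  D_pos_tot <- sum(lib_pool[fraction == "viral_progeny", sorted_depth])
  D_neg_tot <- sum(lib_pool[fraction == "pre_existing_viruses", sorted_depth])
  # placeholder depths when no usable library exists; no ratio is computed
  # in that case (all counts are zero), the value only avoids a 0-depth error
  if (D_pos_tot == 0) D_pos_tot <- 1
  if (D_neg_tot == 0) D_neg_tot <- 1

  all_clusters <- sort(unique(as.data.table(clusters)$cluster_id))
  agg <- usable[, .(
    n_pos = sum(count[fraction == "viral_progeny"]),
    n_neg = sum(count[fraction == "pre_existing_viruses"])
  ), by = cluster_id]
  out <- data.table(cluster_id = all_clusters)
  out <- merge(out, agg, by = "cluster_id", all.x = TRUE)
  out[is.na(n_pos), n_pos := 0L]
  out[is.na(n_neg), n_neg := 0L]
  out[, `:=`(D_pos = D_pos_tot, D_neg = D_neg_tot, n_total = n_pos + n_neg)]

  # reason codes: distinguish "no members in any viral fraction" from
  # "members only at sites lacking a negative viral sort"
  any_viral <- counts[fraction %in% viral_fracs, unique(cluster_id)]
  out[, reason := ifelse(n_total > 0, "ok",
                         ifelse(cluster_id %in% any_viral,
                                "no negative viral library",
                                "no viral-fraction members"))]
  out[, ratio := progeny_ratio(n_pos, n_neg, D_pos, D_neg)]
  out[, ratio_pct := round_half_up(100 * ratio, 2)]
  out[, c("ci_low", "ci_high") := {
    ci <- mapply(function(np, nn, ok, k) {
      if (!ok) return(c(NA_real_, NA_real_))
      bootstrap_ci(np, nn, D_pos_tot, D_neg_tot, n_boot = n_boot,
                   ci_level = ci_level, seed = seed + k)
    }, n_pos, n_neg, reason == "ok", seq_len(.N))
    list(ci[1, ], ci[2, ])
  }]
  setorder(out, cluster_id)
  out[]
}
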