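# viroturn

Viral turnover analysis for BONCAT-FACS sorted viromes.

## What this is for

In a BONCAT (bioorthogonal noncanonical amino acid tagging) seawater
incubation, only proteins made *during* the incubation incorporate the
methionine analog HPG; click-chemistry labeling then lets a cell sorter
(FACS) separate newly produced virions (viral progeny, BONCAT-positive),
pre-existing virions (BONCAT-negative), and active vs inactive microbial
cells into sequenced pools. For microbial ecologists running such
experiments, `viroturn` provides the downstream computational pipeline,
from per-pool contig sets to lineage-level turnover estimates:

* **Consensus viral identification** — a contig is *bona fide* viral when
  flagged by a quorum of detector channels (≥ 2 of e.g.
  VirSorter2/geNomad/CheckV evidence) *and* confirmed by ≥ 2 distinct
  proteins hitting a reference database at ≥ 80 % identity and ≥ 90 %
  coverage, with 1.5 kb / 5 kb reporting and networking tiers.
* **Protein-sharing genome network** — protein clusters (PCs) built with a
  native Markov Cluster (MCL) implementation; genome pairs weighted by the
  hypergeometric tail probability of sharing *c* of *M* protein clusters,
  `weight = min(-log10(p), 300)`; genome communities again by MCL.
* **Viral progeny ratio** — the core turnover statistic, per cluster:

  ```
  R = (n_pos / D_pos) / (n_pos / D_pos + n_neg / D_neg)
  ```

  where `n_pos`, `n_neg` are cluster members from the progeny and
  pre-existing libraries and `D_pos`, `D_neg` the sorted particle depths;
  with bootstrap percentile intervals. Expressed as a percentage, this is
  the per-cluster turnover readout of the whole experiment.
* **Marker & host screens** — gp23 (T4-like capsid marker) screening at
  bit score > 50 and e-value < 1e-10 (strict, as printed); host-linkage
  filtering at ≥ 80 % shared proteins, ≥ 60 % amino-acid identity, ≥ 95 %
  coverage; a neighbor-joining p-distance tree as a desk-scale phylogeny
  stand-in.
* **Fraction summaries** — per-library attrition tables (assembled /
  ≥ 5 kb / viral / viral ≥ 1.5 kb / viral ≥ 5 kb with the headline
  percentage) and composition statistics.
* **Synthetic community simulator** — ground-truth lineages with turnover
  probabilities θ, multinomial sorting at exact depths, lognormal contig
  lengths, gamma amplification bias and per-detector noise, so the whole
  pipeline is testable end to end (parameter recovery of θ included)
  without any sequencing data.

See `vignettes/viroturn-methods.Rmd` for the model, assumptions,
parameter choices and limitations.

## Worked example

Simulate a four-fraction coastal sort (three viral lineages with
turnover θ = 0.9 / 0.5 / 0.1, two host lineages; 100,000 progeny and
50,000 pre-existing virions, 25,000 active and inactive cells) and run
the pipeline:

```r
library(viroturn)
spec <- default_community_spec(seed = 7)
sim  <- simulate_community(spec)
res  <- run_pipeline(sim$contigs, sim$evidence, sim$hits, spec$libraries,
                     config = run_config(n_boot = 500, seed = 7))
res$summary
#>    library_id assembled assembled_5kb viral viral_1500 viral_5kb viral_5kb_pct
#> 1:   act_cell       375           272   181        180       126          46.3
#> 2: inact_cell       375           270     3          3         3           1.1
#> 3:    neg_vlp       750           558   742        735       550          98.6
#> 4:    pos_vlp      1500          1127  1484       1466      1115          98.9
res$ratios[, .(cluster_id, n_pos, n_neg, n_total, ratio_pct, ci_low, ci_high)]
#>    cluster_id n_pos n_neg n_total ratio_pct     ci_low   ci_high
#> 1:       VC_1   662    30     692     91.69 0.88813097 0.9438202
#> 2:       VC_2   374   173     547     51.94 0.47638327 0.5640310
#> 3:       VC_3    79   347     426     10.22 0.07913029 0.1240106
```

Reading the output: each genome cluster's `ratio_pct` is the
depth-normalised share of newly produced virions. The three MCL clusters
recover the three planted lineages, and their ratios estimate the true
turnover probabilities (91.7 %, 51.9 %, 10.2 % for θ = 0.9, 0.5, 0.1) —
a fast-turnover lineage, an intermediate one, and a mostly-dormant one.
The summary table shows viral content concentrating in the viral sorts
and in *active* cells (46.3 %) but not inactive ones (1.1 %), the
active-infection signal the cell fractions are sorted to expose.

The statistic itself on published-scale inputs — a 17-member cluster
splitting 15 progeny / 2 pre-existing at depths 100,000 / 50,000:

```r
progeny_ratio_pct(15, 2, 100000, 50000)
#> [1] 78.95
```

## Command line

A thin CLI wraps the main stages (`simulate`, `call-viral`, `summarize`,
`network`, `ratio`, `screen`, `tree`):

```sh
Rscript inst/scripts/viroturn simulate --outdir sim_out --seed 1
Rscript inst/scripts/viroturn screen --hits sim_out/hits.tsv --mode gp23 --out markers.tsv
```
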