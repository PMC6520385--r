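# propscreen

Marker discovery for differentiation propensity of human induced
pluripotent stem cell (hiPSC) lines. Given probe-level expression of
undifferentiated lines, a trilineage qPCR panel measured after embryoid-body
differentiation, and (optionally) two-group HumanMethylation450-style beta
matrices, `propscreen` reproduces a complete screening workflow:

1. **Normalisation + three-step probe filter** — per-array global scaling to
   a trimmed mean of 500, then present-call (`"P"` in ≥ 4 of 6 replicates of
   ≥ 1 line), one-way ANOVA across lines (P < 0.05), and a ≥ 5-fold range of
   line means.
2. **Propensity ranking** — comparative-Ct quantification
   (fold = 2^−ΔΔCt against GAPDH, anchored to the 201B7 reference line),
   per-gene z-scoring, PCA per germ-layer panel, lines ranked by descending
   PC1.
3. **Exact Spearman screen** — each probe's line-mean expression rank is
   correlated with each lineage's propensity rank; significance uses the
   exact permutation null (all 10! permutations enumerated in C++), whose
   two-sided α = 0.05 critical value at n = 10 is |r_s| ≥ 0.648. Signed
   candidate sets are intersected to find *switch markers*: genes positively
   correlated with ectoderm and negatively with mesoderm/endoderm propensity
   (or the mirror).
4. **Differential methylation** — detection-P and annotation filters,
   per-probe pooled t tests, Benjamini–Hochberg q-values, hyper/hypo calls
   at q < 0.05 and |log2 FC| > 0.6 (both strict), seven-category genomic
   region distributions, and per-gene island/shore tracks.

A synthetic-data generator (`sim_config()`, `simulate_*()`) produces inputs
with the statistical structure the analysis assumes — coupled lineage
propensities, rank-level planted markers, planted gene-body
hypermethylation — so the whole pipeline is testable offline.

## Worked example

```r
library(propscreen)

cfg <- sim_config(
  n_probes = 2000, seed = 42,
  planted_markers = list(planted_marker(
    "P00001", c(ectoderm = 0.9, mesoderm = -0.9, endoderm = -0.9),
    gene = "SWITCH1")))

prop <- simulate_propensities(cfg)          # coupled latent propensities
expr <- global_scale(simulate_expression(cfg, prop))
flt  <- filter_probes(expr)
flt$counts
#>   input present   anova    fold
#>    2000    1400      74       1

ct <- simulate_panel_cts(cfg, prop)
rk <- propensity_ranking(ct, attr(ct, "panel"))
interlineage_rank_correlation(rk)
#>   lineage1 lineage2        r_s          p
#> 1 ectoderm mesoderm -0.4060606 0.24747079
#> 2 ectoderm endoderm -0.4181818 0.23253693
#> 3 mesoderm endoderm  0.7454545 0.01740575

scr <- screen_markers(expr, flt$steps$fold, rk, annotation = expr$annotation)
top_k_table(scr, 5)
#>    lineage     sign rank    gene  probe        r_s
#> 1 ectoderm positive    1 SWITCH1 P00001  0.6848485
#> 2 mesoderm negative    1 SWITCH1 P00001 -0.8181818
#> 3 endoderm negative    1 SWITCH1 P00001 -0.8303030

inverse_correlation_intersection(scr)$ecto_positive
#> [1] "SWITCH1"
```

The filter narrows 2,000 probes to the single planted switch marker (1,400
survive the present-call step, 74 the ANOVA — about the 5% expected for
null probes — and only the planted probe spans a 5-fold range). The screen
then flags it significantly positive for ectoderm and negative for
mesoderm/endoderm (every |r_s| above the exact critical value 0.648), and
the signed-set intersection names it as the sole switch-marker candidate —
the synthetic analogue of finding one gene with inverse lineage
correlations in a real cohort. The mesoderm–endoderm propensity ranks
correlate positively (r_s = 0.75, exact P = 0.017): lines good at mesoderm
are good at endoderm and poor at ectoderm.

Methylation, on the same seed:

```r
meth <- simulate_methylation(cfg)
keep <- annotation_filter(detection_filter(meth), meth$manifest)
dm   <- differential_methylation(meth, keep)
summarize_fractions(dm)[1:2]
#> $pct_differential
#> [1] 3.603604
#>
#> $pct_hyper_among_differential
#> [1] 86.11111
region_distribution(dm, meth$manifest, "hyper")["Gene body"]
#> Gene body
#>       100
```

3.6% of assessed probes change methylation, 86% of them hypermethylated,
all in gene bodies — by construction, mirroring a knockdown that promotes
gene-body CpG methylation.

## Command line

```sh
exec/propensity-screen run --config inst/extdata/example-config.json \
    --seed 42 --out-dir out/
```

Subcommands `simulate`, `filter`, `rank`, `screen`, `methylation`, `run`;
artifacts (TSV/CSV/JSON, including `run_report.json` with the seed and all
thresholds) are written to `--out-dir`, logs to stderr.

## Method documentation

See `vignettes/propensity-screening.Rmd` for the model, the exact-null
construction, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and known limitations.
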