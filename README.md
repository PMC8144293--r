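# coresweep

Gut microbiome studies routinely reduce an ASV table to a "common core"
by keeping only taxa whose prevalence — the fraction of host individuals
in which a taxon is detected — exceeds a threshold. Thresholds in the
literature range from 10% to 90%, which raises a practical question for
anyone comparing core microbiomes across studies or host species: **how
much does the choice of prevalence threshold distort alpha diversity and
beta dissimilarity, and which measures are robust to it?**

`coresweep` is an R package plus analysis workflow for that question,
aimed at microbial ecologists working with sample-by-ASV count tables and
a rooted phylogeny. It provides:

* **Eight diversity measures spanning the weighting space** — alpha:
  observed richness, Shannon, Faith's PD, balance-weighted phylogenetic
  diversity (BWPD); beta: Jaccard, Morisita, unweighted and weighted
  UniFrac (plus Bray–Curtis for redundancy checks) — built on one shared
  edge-mass kernel. For edge *e* with branch length ℓₑ and descendant
  relative-abundance mass pₑ:

  - Faith's PD = Σ ℓₑ over edges with pₑ > 0 (root path included)
  - BWPD_θ = Σ ℓₑ (2·min(pₑ, 1−pₑ))^θ, default θ = 0.5
  - unweighted UniFrac = Σ ℓₑ (edges unique to one sample) / Σ ℓₑ (either)
  - weighted UniFrac = Σ ℓₑ |pₑˣ − pₑʸ| / Σ ℓₑ (pₑˣ + pₑʸ) (normalized form)

* **Macroecological diagnostics**: exact (hypergeometric) and subsampled
  rarefaction curves, sample-accumulation curves with exact expectations,
  first-order jackknife pool extrapolation S_jack1 = S_obs + f₁(n−1)/n
  and its sample-size dependence, occupancy–abundance and rank–abundance
  curves, prevalence-class distributions.

* **The prevalence sweep**: rarefy to 10,000 reads, filter the rarefied
  table at thresholds 0–90% in 10% steps, score everything per sample,
  standardize per dataset × metric, then compare — Bartlett variance
  profiles across thresholds, Spearman correlations of filtered vs
  unfiltered scores, and read-depth bias checks.

* **A seeded synthetic ASV generator** (lognormal metacommunity,
  negative-binomial sampling with closed-form occupancy, injected
  sample-private taxa) whose eight presets emulate published human and
  wildlife gut datasets, so the entire workflow is testable offline.

## Worked example

```r
library(coresweep)

# hand-checkable metrics on a four-leaf tree
tree <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
faith_pd(c(A = 1, B = 1), tree)
#> [1] 3
weighted_unifrac(c(A = 1), c(B = 1), tree)
#> [1] 0.5

# a synthetic host dataset: 40 individuals, 25% of each sample's ASVs private
params <- synth_params(label = "demo", n_samples = 40, u = 0.25, seed = 7)
ds <- generate_table(params)
dim(ds$table)
#> [1]   40 3540

macro_summary(ds$table)[, c("S_obs", "jack1", "pct_pool_detected", "pct_per_sample_unique")]
#>   S_obs  jack1 pct_pool_detected pct_per_sample_unique
#> 1  3540 6601.5          53.62418              25.08216

# the sweep: rarefy to 10,000, filter at 0-90% prevalence, score, compare
sw <- run_study(list(demo = ds), sweep_config(seed = 7))
cc <- core_vs_unfiltered(sw)
round(with(aggregate(rho ~ threshold, cc, mean), setNames(rho, threshold)), 2)
#>  0.1  0.2  0.3  0.4  0.5  0.6  0.7  0.8
#> 0.94 0.93 0.93 0.92 0.88 0.81 0.63 0.27

vp <- variance_profile(standardize(sw))
vp[order(vp$statistic), c("metric", "statistic", "df")]
#>               metric   statistic df
#> 1               bwpd   0.8003113  8
#> 6            shannon   1.2637533  8
#> 8   weighted_unifrac  18.7191253  8
#> 4           morisita  27.3299561  8
#> 2           faith_pd 158.1306958  8
#> 7 unweighted_unifrac 221.9072419  8
#> 5  observed_richness 266.3448784  8
#> 3            jaccard 302.6974796  8
```

Reading the output: 3,540 ASVs were observed but the jackknife-1
extrapolation predicts ~6,600 — only 54% of the pool was detected,
because a quarter of each host's ASVs occur in that host alone. Sample
rankings under filtering stay nearly intact up to a 50% prevalence
threshold (ρ ≥ 0.88) and then collapse (ρ = 0.27 at 80%). The Bartlett
statistics show which measures' across-sample variation is distorted by
filtering: smallest for BWPD and weighted UniFrac among the
phylogeny-aware measures, largest for richness, Jaccard and unweighted
UniFrac.

## Analysis workflow

The `analysis/` scripts run the full study on the eight synthetic
presets, writing tidy TSVs under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1            # results/synth/<dataset>/
Rscript analysis/02_macroecology.R --seed 1        # results/macroecology/
Rscript analysis/03_sweep.R --seed 1               # results/sweep/sweep_scores.tsv, variance_profile.tsv
Rscript analysis/04_threshold_comparisons.R        # core_correlations.tsv, depth_bias.tsv
```

## Limitations

The generator draws samples independently from one metacommunity: no
host-level compositional heterogeneity and no abundant-but-patchy taxa.
Purely abundance-weighted measures (Shannon, Morisita) are therefore
less threshold-sensitive on synthetic data than on real gut datasets;
see the methods vignette (`vignettes/prevalence-thresholds.Rmd`) for the
full account of the model, parameter defaults, and design choices.
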