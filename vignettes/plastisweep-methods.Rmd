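---
title: "Methods: plasticity screens and sweep scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasticity screens and sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastisweep)
```

# Overview

`plastisweep` implements two complementary analyses of a highland/lowland
reciprocal-transplant experiment on two chicken populations:

1. a **transcriptome screen** that separates environment-driven expression
   changes from breed-intrinsic ones, yielding *environment-driven miRNAs*
   (ENMs); and
2. a **genome scan** for selective sweeps, contrasting the two populations
   with windowed Weir–Cockerham $F_{ST}$ and nucleotide diversity $\pi$.

Both halves are backed by simulators with known ground truth, so every stage
is testable without external data.

# The experimental design

Two breeds (`TIB`, a highland breed, and `PX`, a lowland breed) are each
raised in two environments (`HIGH` and `LOW`), giving four groups:

| group | breed | environment |
|-------|-------|-------------|
| `TC`  | TIB   | HIGH        |
| `LTC` | TIB   | LOW         |
| `HLC` | PX    | HIGH        |
| `LC`  | PX    | LOW         |

`make_sample_design()` builds this layout for one or more tissues with a
fixed number of replicates. The six pairwise group comparisons differ in
which factors they confound. `build_screen_design()` derives, for each
comparison, whether the two groups differ in breed (`BR`), rearing
environment (`EN`), or embryonic/egg environment (`EE`) — purely from the
group composition, never from a hard-coded list. A comparison is
**effective** for the screen when the two groups differ in environment;
`TC–HLC` and `LTC–LC` compare groups reared in the same environment and are
**ineffective**.

# Normalization

`tmm_factors()` implements trimmed-mean-of-M normalization. For sample $k$
against reference $r$ (chosen as the sample whose 75th-percentile count
fraction is closest to the mean of those fractions), features expressed in
both samples contribute log-ratios
$M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}$ and average abundances $A_g$.
The most extreme 30% of $M$ values (each side) and 5% of $A$ values are
trimmed, and the remaining $M_g$ are combined with inverse
binomial-variance weights. Factors are rescaled so their geometric mean is
1. `cpm_matrix()` divides by effective library sizes
(library size × factor); the log variant computes
$\log_2\!\big(\frac{y + p_j}{N_j^{\text{eff}} + 2p_j}\cdot 10^6\big)$ with a
prior count $p_j$ scaled proportionally to each library's size (default
prior 2), which keeps zeros finite without biasing large libraries.

# The exact negative-binomial test

Counts in group $g$ are modelled as NB with mean $\mu$ and dispersion
$\varphi$, so $\mathrm{Var} = \mu + \varphi\mu^2$.

* **Dispersion** is estimated by a conditional maximum likelihood on
  *pseudo-counts*: `pseudo_counts()` uses a quantile-to-quantile mapping
  (`q2q_nbinom()`, the average of a normal and a gamma approximation applied
  to both tails) to adjust each sample's counts to a common library size.
  `estimate_common_dispersion()` maximizes the conditional log-likelihood on
  a log-spaced grid ($10^{-4}$ to $10$) followed by `optimize()` refinement;
  estimates at the lower grid edge are reported as 0.
* **Testing**: for a feature with group sums $(s_A, s_B)$, the conditional
  distribution of $s_A$ given $s_A+s_B$ under equal means has
  negative-hypergeometric form; `exact_split_pvalue()` computes it with
  log-gamma weights. The two-sided p-value is the **doubled smaller tail**,
  $p = \min(1,\; 2\min(P_{\le s_A}, P_{\ge s_A}))$. We chose doubling over
  the "sum of outcomes at most as probable" convention because it is
  monotone in the observed split and exactly matches the doubled-tail
  binomial test at $\varphi = 0$ — a property we verify in the tests.
  At $\varphi = 0$ the conditional law reduces to a binomial split.
* **Effect sizes**: `logFC` uses a small prior count (0.125) on each group
  mean CPM; `logCPM` uses prior 2.

`call_dems()` applies the differential-expression thresholds: a feature is
a DEM when $|\log_2 FC| \ge 1.5$, $\log_2\text{CPM} > 2$ (strict), and
Benjamini–Hochberg FDR $\le 0.05$. Boundary semantics are deliberate and
tested: the fold-change and FDR cutoffs are inclusive, the abundance cutoff
is exclusive.

A simpler per-feature screen, `deg_ttest()`, runs row-wise Welch t-tests on
(log) expression with Bonferroni correction and a fold-change filter
(FC $\ge 2$ or $\le 0.5$); degenerate zero-variance rows resolve to $p = 1$
when the groups are identical and $p = 0$ when they are separated.

# The ENM screen

`screen_enm()` takes one DE table per comparison and keeps a feature iff it
is differentially expressed in **all four effective** comparisons and in
**neither ineffective** comparison. Requiring DE in the ineffective
comparisons to be absent removes breed-intrinsic differences: a feature
that differs between `TC` and `HLC` (same environment, different breed)
reflects breed, not plasticity.

Each candidate gets an `altitude_preference`: `HIGH` if it is up in the
high-environment group in all four effective comparisons, `LOW` if down in
all four, and `INCONSISTENT` otherwise (kept, but flagged). Comparison
orientation is canonicalized internally, so reversed input tables with
flipped directions give identical results.

# ANOVA confirmation

Candidates are confirmed with a balanced two-way ANOVA
(`two_way_anova()`, via `stats::aov`) on **log2-CPM** — the scale on which
expression effects are approximately additive and homoscedastic. A
candidate is a final ENM iff the environment main effect is significant
($p_{env} \le \alpha$, default 0.05) **and** the breed main effect is not
($p_{breed} > \alpha$). The interaction is reported but not used for the
call, because a breed-specific *response* to environment is still an
environmental effect. Degenerate fits follow documented conventions: a
zero-SS effect over a zero residual gives $F = 0, p = 1$; a non-zero effect
over a zero residual gives $F = \infty, p = 0$.

# The sweep scan

`sweep_scan()` tiles each chromosome with sliding windows (default 40 kb
windows, 20 kb step, starting at position 1; a terminal window that
overhangs the chromosome end is flagged `partial` and excluded from region
calling by default). Per window:

* **$F_{ST}$**: per-site Weir–Cockerham (1984) variance components for two
  populations, $a$ (among-population) and $d = a+b+c$ (total), computed by
  `site_fst_components()` from sample sizes, alternate-allele counts and
  heterozygote counts. The window estimate is the **ratio of sums**
  $\sum a / \sum d$, clamped to $[0, 1]$ — ratio-of-sums is less biased
  than averaging per-site ratios. Sites monomorphic across both
  populations contribute $(0, 0)$; sites with fewer than one called diploid
  in a population are `NA`.
* **$\pi$** per population: $\sum_g 2\hat p_g(1-\hat p_g)\frac{2n}{2n-1}$
  divided by the window length (so monomorphic stretches dilute diversity),
  with the standard small-sample correction.
* **`pi_ratio`** $= \pi_{pop2}/\pi_{pop1}$ where `pop1` is the
  selected/highland population — so a sweep in `pop1` (reduced diversity)
  inflates the ratio above 1.

`call_regions()` thresholds windows at $F_{ST} \ge$ `fst_threshold`
(default 0.3) first, then merges overlapping qualifying windows into
regions (`GenomicRanges::reduce`), reporting window count and peak
$F_{ST}$ per region. Thresholding *windows first*, then merging, is the
deliberate interpretation: it keeps region boundaries tied to evidence
rather than extending regions through sub-threshold windows.
`annotate_regions()` attaches gene identifiers from a data frame or a
BED/GFF/GTF file (via `rtracklayer`) for any overlap of at least one base.

# Simulators

`simulate_counts()` draws NB counts with variance $\mu + \varphi\mu^2$.
Baseline log2 means are uniform in a configurable range; a fraction of
features receive symmetric $\pm$`effect_log2fc`$/2$ offsets keyed to
environment (`EN`), breed (`BR`), or only the `TIB`+`HIGH` cell (`INT`).
Library sizes are uniform in a range. The truth object records each
feature's class and direction.

`simulate_genotypes()` draws diploid dosages Binomial$(2, p)$ per
individual. Neutral sites share one frequency per site
(Beta$(2,2)$ truncated to $[0.02, 0.98]$) between populations; diverged
windows (aligned to span boundaries, non-overlapping) shift the two
populations to $p \pm \delta/2$ (clipped). `diverged_delta = 0` yields an
all-neutral truth.

**Scope and limits**: the count simulator has no per-feature dispersion
trends, GC/length biases, or sample outliers; the genotype simulator has no
linkage disequilibrium, mutation/recombination model, or demography — sites
are exchangeable given their frequencies. They are designed for
calibration and recovery testing of *these* estimators, not as general
sequencing simulators. All simulation runs are reproducible: parameters
carry a seed and `with_seed()` restores the caller's RNG state.

# Pipelines and determinism

`run_transcriptome()` chains normalization, dispersion estimation, the six
exact tests, DEM calling, the ENM screen and the ANOVA confirmation per
tissue; `run_sweep()` chains VCF reading, the window scan, region calling
and annotation. Configuration is a validated YAML file or list
(`pipeline_config()`; unknown keys are errors). Every output TSV carries a
header line with the package version, an MD5 hash of the resolved
configuration and the seed, and repeated runs of the same configuration are
byte-identical — a property asserted in the test suite.

# Default parameters at a glance

| parameter | default | rationale |
|---|---|---|
| TMM log-ratio trim | 30% | robust against asymmetric DE |
| TMM abundance trim | 5% | drops extreme-abundance features |
| CPM prior count | 2 | finite log-CPM for zeros |
| logFC prior | 0.125 | shrinks fold changes of tiny counts |
| DEM: min \|log2FC\| | 1.5 | ≈ 2.8-fold, inclusive |
| DEM: min logCPM | 2 (strict) | ≈ 4 CPM expression floor |
| DEM: max FDR | 0.05 | Benjamini–Hochberg, inclusive |
| t-test screen | FC ≥ 2, Bonferroni α 0.05 | conservative per-tissue screen |
| ANOVA α | 0.05 | both main-effect decisions |
| window / step | 40 kb / 20 kb | half-overlapping tiling |
| $F_{ST}$ threshold | 0.3 | strong-differentiation cutoff |

# A worked example

```{r example, eval = FALSE}
design <- make_sample_design(tissues = "liver")
sim <- simulate_counts(count_sim_params(n_features = 1000, frac_en = 0.05,
                                        seed = 7), design)
norm <- tmm_factors(sim$counts)
phi <- estimate_common_dispersion(sim$counts, design$group, norm)
screen <- build_screen_design(design)
de_sets <- setNames(lapply(seq_len(nrow(screen)), function(i) {
  a <- design$sample_id[design$group == screen$group_a[i]]
  b <- design$sample_id[design$group == screen$group_b[i]]
  call_dems(nb_exact_test(sim$counts, a, b, phi))
}), screen$comparison)
cand <- screen_enm(de_sets, screen)
lcpm <- cpm_matrix(sim$counts, norm, log = TRUE)
classify_candidates(cand, anova_table(lcpm, design, cand$feature))
```
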