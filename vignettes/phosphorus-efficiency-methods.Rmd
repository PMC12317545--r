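---
title: "Phosphorus-efficiency screening and marker-trait association: models and methods"
author: "phosGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphorus-efficiency screening and marker-trait association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosGWAS)
```

# The screening design

`phosGWAS` targets the standard two-treatment pot screen for phosphorus
efficiency in crop diversity panels: every genotype is grown under a
high-P control (**HP**) and a low-P stress treatment (**LP**) in `R`
replicated blocks, and a battery of traits is measured per pot — fresh and
dry biomass of shoot, root and tubers (g), plant heights (cm), root length
(cm) and shoot P concentration (mg per 100 g dry matter). The package's
canonical phenotype container is a validated long table (one row per
genotype × treatment × replicate × trait); missing measurements are carried
as explicit `NA` and never imputed at I/O time.

Two traits are derived, per pot, from the measured ones:

* `Pupt = P_conc × SDW / 100` — phosphorus uptake in mg per plant (the
  concentration refers to 100 g of dry matter, so the factor 100 converts
  units);
* `PUE = SDW / Pupt` — utilization efficiency in g biomass per mg P.

Substituting one definition into the other gives `PUE × P_conc = 100`
identically, which the test suite asserts on every derived record: the two
formulas are unit conversions of the same measurement, and any violation
would indicate a derivation bug. Division guards return missing values
(never infinities) when `Pupt` or `SDW` is zero. Root:shoot ratio and
biomass totals are derived the same way. Because derived traits are always
computed downstream — the simulator never draws them directly — these
identities hold exactly on synthetic data too.

# Variance partitioning and heritability

Per trait, the package fits the fixed-effects two-way ANOVA with a
replicate block term using `stats::aov`:

```
value ~ replicate (E) + genotype (G) + treatment (T) + G:T
```

on a *balanced complete* design; unbalanced inputs are rejected rather than
silently approximated, because the moment estimators below assume balance.
From the mean squares, with `T` treatments and `R` replicates:

$$\sigma^2_G = \frac{MSQ_G - MSQ_{GT}}{T\,R},\qquad
  \sigma^2_{GT} = \frac{MSQ_{GT} - MSQ_{Re}}{R},\qquad
  \sigma^2_{Re} = MSQ_{Re},$$

$$\sigma^2_P = \sigma^2_G + \frac{\sigma^2_{GT}}{T} +
  \frac{\sigma^2_{Re}}{T\,R},\qquad
  H^2_{bs} = \frac{\sigma^2_G}{\sigma^2_P}.$$

The replicate block is tested but deliberately excluded from the component
formulas — exactly what the printed estimators imply. Negative raw moment
estimates (possible whenever `MSQ_G < MSQ_GT` or `MSQ_GT < MSQ_Re`) are
clamped to zero for reporting, the standard practice that also keeps the
reported `H²_bs` inside `[0, 1]`; the raw values are retained in the result
for diagnostics. When every observation is identical the partition is
reported as exact zeros with missing F statistics rather than as ratios of
rounding noise.

These estimators are unbiased for the generating variances under the
simulator's model (below), so heritability recovery is a sharp end-to-end
check: the suite simulates 200 panels of 200 genotypes (`T = R = 2`) at
each of `H² ∈ {0.3, 0.6, 0.9}` and requires the mean estimate within
±0.05 of truth. The panel count and size were chosen so the Monte-Carlo
error of that mean (≈0.005) is well below the tolerance.

# Stress-tolerance scores

The per-trait stress tolerance index for genotype *i* is

$$STI_i = \frac{Y_{pi}\, Y_{si}}{(\overline{Y_p})^2},$$

with `Y_pi`/`Y_si` the genotype's HP/LP means and `Ȳ_p` the HP mean over
**all** genotypes with an HP value — not only those with complete data —
because the denominator is defined as the panel's control performance. STI
is invariant to the trait's units and equals 1 for a genotype sitting at
the panel mean under both regimes. Genotypes missing either treatment are
excluded and listed.

The membership-function composite (MFVP) min–max rescales each trait's STI
over the genotype set,

$$U_{ij} = \frac{STI_{ij} - STI_{j\min}}{STI_{j\max} - STI_{j\min}},\qquad
  U_i = \frac{1}{n}\sum_{j=1}^{n} U_{ij},$$

over a configurable trait set defaulting to shoot, root and total dry
weight plus P uptake. Only the genotype intersection of all STI tables
enters; a trait with constant STI carries no ranking information and drops
out of the average (reducing `n`) instead of contributing an arbitrary
constant. Ranking ties are broken lexicographically by genotype id so
top-k/bottom-k lists are reproducible run to run.

The STI input is the genotype *mean* per treatment (not pooled
replicates): means are what the rest of the pipeline consumes, and the
score is a ratio of means by definition.

# Performance clustering

Genotype profiles over the tolerance trait set × both treatments are
z-standardized per column (sample SD; constant columns become zeros with a
warning). Missing cells are imputed by the column mean *before* scaling —
the matrix must be complete for distance computation — with the imputation
count recorded. Clustering is agglomerative on Euclidean distances with
complete linkage by default (configurable to average or Ward): the linkage
default of the heatmap tool family this reproduces. The tree is cut at
`k_main = 2` and `k_sub = 9` by default; sub-cluster labels are renumbered
by dendrogram leaf order, making assignments deterministic for a given
input order, and the main cut provably coarsens the sub-cut.

Published screens label their clusters best/intermediate/worst
narratively; to make that reproducible the package ranks sub-clusters by
their average rank across all (trait, treatment) mean columns and splits
the ranking into terciles — top tercile `best`, bottom `worst`, middle
`intermediate` (a single cluster is `intermediate` by convention). With
two clusters this degenerates to best/worst, matching intuition.

# The association scan

**QC.** Markers are filtered by call rate first (fraction of non-missing
calls `< 0.85` discarded), then by folded minor-allele frequency over the
non-missing calls (`< 0.05` discarded). Both bounds are strict — a marker
exactly at the threshold is kept — and each marker is counted in exactly
one removal bin, so `markers_in = markers_out + removed_call_rate +
removed_maf` always reconciles. Missing calls are then replaced by the
marker's mean dosage, the simplest imputation that leaves observed column
means unchanged.

**Model.** The scan is a single-marker ordinary least-squares regression of
the phenotype on (intercept, principal-component covariates, dosage), per
marker, with the dosage coefficient's two-sided t-test reported.
Multi-locus scanners used in practice are external algorithms with many
tuning choices; a PC-adjusted single-marker scan is transparent, exactly
reproducible, and its statistical properties are verifiable (the suite
checks coefficient, SE and p against `lm()` and type-I error ≈ 0.05 under
the global null). Three PCs of the centered dosage matrix are the default
structure control. Computationally the scan residualizes the phenotype and
all markers on the covariate block once (Frisch–Waugh), which reproduces
full-model OLS exactly while staying vectorized over thousands of markers.
Scanned contexts per trait are the HP and LP genotype means, their
difference, and the trait's STI.

**Significance.** Family-wise control is the Bonferroni rule on the
`−log10` scale: a record is significant iff `−log10(p) > −log10(α/M)` with
`M` the number of valid tests, strictly (a marker at exactly `p = α/M` is
not significant). At `α = 0.05` and `M ≈ 4800` the threshold is ≈ 4.98.

**PVE.** The variance explained by a SNP is estimated from the scan
statistics as

$$PVE = \frac{2\beta^2 f(1-f)}
  {2\beta^2 f(1-f) + SE(\beta)^2\, 2N\, f(1-f)}
  = \frac{\beta^2}{\beta^2 + N\,SE(\beta)^2},$$

the default `"shim"` variant, in which the allele-frequency factor cancels.
A second variant `"as_printed"` replaces the first denominator term by
`2β²(1−f)` — the form in which the expression is commonly typeset, one MAF
factor short of cancelling. Both are exposed because published PVE values
may follow either; they agree at `f = 0.5` up to the factor shown in the
examples (`β = 1, SE = 0.1, f = 0.5, N = 200` gives 1/3 vs. 1/4).

**Candidate genes.** For a significant SNP, genes whose 1-based inclusive
span overlaps `[pos − 1 Mb, pos + 1 Mb]` on the same chromosome are
returned, sorted by distance (0 when the SNP lies inside the gene). All
coordinates in the package are 1-based inclusive (VCF/GFF3 convention) to
keep window queries free of off-by-one errors.

# The synthetic-data generator

The generator exists so that every stage has ground truth. Phenotypes
follow the same model the ANOVA assumes,

$$y_{itr} = \mu_t + g_i + (gt)_{it} + \textstyle\sum_m \beta_m x_{im}
  \,[t\ \text{targeted}] + \varepsilon_{itr},$$

with `g ~ N(0, σ_G²)`, `(gt) ~ N(0, σ_GT²)`, `ε ~ N(0, σ_Re²)` per trait,
a balanced table by default, and negative draws for non-negative traits
truncated at zero (truncation is counted in the ground truth; at the
default settings it is rare for every trait except the low LP biomass
means, where it mimics real near-zero stress phenotypes). The implied
heritability `σ_G²/(σ_G² + σ_GT²/T + σ_Re²/(TR))` is part of the returned
truth. Default trait parameters emulate a greenhouse potato P-starvation
screen: HP means well above LP means for biomass, height and P
concentration, and SDs sized for moderate-to-high heritability (≈0.5–0.8).
Treatment enters through per-treatment grand means rather than a
multiplicative stress factor — the simplest structure consistent with the
ANOVA model. P uptake and PUE are never drawn directly, so their
derivation identities hold exactly.

Genotypes follow a star-shaped island model: per marker an ancestral
frequency `p ~ U(0.05, 0.95)`, subpopulation frequencies
`Beta(p(1−F)/F, (1−p)(1−F)/F)` so that `F` acts as an Fst-like divergence
parameter, dosages `Binomial(2, p_k)`, and uniform random masking at the
missing rate. Defaults (200 samples, 4,800 markers on 12 chromosomes,
`K = 3`, `F = 0.1`, 3% missing) produce a panel whose PCA shows clear but
not dominant structure, like a diverse crop collection. Planted marker
effects add `β` trait units per alternate-allele copy to the targeted
treatment(s) and are recorded with their realized MAF. Phenotype and
genotype noise use independent seed streams, so the same phenotype panel
can be generated with or without genotypes.

What the generator deliberately does **not** emulate: linkage
disequilibrium along chromosomes (markers are independent given the
subpopulation frequencies), tetrasomic inheritance (dosages are
diploidized, as GBS consensus calling typically emits; a ploidy switch
exists for 0–4 dosages), treatment-specific variances (real LP
measurements are markedly less dispersed than HP ones), and measurement
error structure such as pot or position effects. Consequently, passing
tests demonstrate correctness of the statistical machinery under its own
assumptions — not that any particular real panel will show the same
heritabilities or hit counts. Ratio traits are a visible instance: with
independently simulated shoot and root weights, per-genotype root:shoot
changes have heavy tails whenever a stressed shoot mean approaches zero,
which is why the ratio-of-means summary is offered alongside the
per-genotype mean in `changeMetrics()`.

# Numerical choices and edge cases

* Dosages are stored as doubles in `[0, ploidy]`; raw calls are integers,
  imputed matrices fractional. VCF output refuses fractional dosages.
* Marker maps are kept sorted by (chromosome, position), numeric
  chromosome labels first in numeric order, then lexicographic.
* Scan degeneracies: a marker constant across scanned samples (or
  numerically collinear with the covariates, residual sum of squares below
  `√eps`) yields a flagged record with missing p; a constant phenotype
  yields zero effects with missing p.
* Strictness conventions: QC thresholds keep markers exactly at the bound;
  Bonferroni significance requires `p` strictly below `α/M`.
* All ranking ties (MFVP, candidate-gene distance) have documented
  deterministic tie-breaks.
* Every simulation function takes an explicit integer seed and derives
  independent stream seeds from it; identical `(config, seed)` give
  byte-identical outputs, which the pipeline tests assert on whole output
  directories.

# Detection power at realistic effect sizes

Published single-SNP PVE values for P-efficiency traits sit around
7–11%. For a marker explaining a fraction `PVE` of the scanned phenotypic
variance, the expected squared t statistic is approximately
`N·PVE/(1−PVE)`; at `N = 200` and `PVE = 0.10` that is ≈22, i.e.
`|t| ≈ 4.7` and `−log10 p ≈ 5.3`, while the smallest of ~4,800 null
p-values sits near `−log10 p ≈ 3.9` and the Bonferroni cut at ≈4.98. An
effect of that size is therefore expected to top the scan in roughly
two-thirds to three-quarters of replicate studies and to cross the
genome-wide threshold in about half — detection of ~10%-PVE effects at
panels of 200 is genuinely borderline, which is worth keeping in mind when
interpreting both the acceptance simulations (which measure exactly these
rates) and real screens of this size. Larger effects (PVE ≳ 15%) are
detected essentially always, as the README's worked example shows.

# Limitations

* The variance-component estimators require a balanced design; unbalanced
  screens must be subset first (the ANOVA rejects them explicitly).
* The scan is single-marker OLS with PC adjustment; it does not model
  kinship, multi-locus effects or LD, and its hit lists are not expected
  to coincide with multi-locus scanners on the same data. A config hook
  allows plugging an external scanner into the pipeline's record format.
* PVE estimates inherit single-marker bias (winner's curse at selected
  hits).
* Cluster memberships depend on linkage and distance choices; only the
  partition structure, not specific published memberships, is a supported
  target.
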