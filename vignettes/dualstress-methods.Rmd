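---
title: "Statistical methods in dualstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in dualstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualstress)
```

# The experiment this package models

`dualstress` analyses a dual-stress Arabidopsis experiment in which plants
were attacked either by a chewing herbivore (*Spodoptera exigua*
caterpillars, `Spod`) or by an avirulent bacterial pathogen (*Pseudomonas
syringae* pv. *tomato*, `Psyr`), and responses were profiled on two-color
cDNA microarrays over a time course and by LC-MS metabolite profiling at a
single late time point. Two properties of that design drive everything in
the package:

* **Arrays are treatment-control pairs.** Treated RNA is always labeled with
  Cy3 (532 nm) and the matching control RNA with Cy5 (635 nm) on the same
  slide, so the natural response variable is the per-spot ratio
  $\log_2(\mathrm{Cy3}/\mathrm{Cy5})$: a paired contrast that cancels
  probe-specific hybridization efficiency.
* **The design is a balanced factorial**: 2 experimental runs x 2
  treatments x 3 sampling times (1, 6, 24 h) x 5 biological replicates = 60
  arrays, each printed with 1287 experimental probe spots of which 26 probes
  are duplicated (1261 unique probes), plus spike, poly(dA), blank, buffer
  and negative control spots. The metabolite arm is 2 runs x 2 treatments x
  treated/control x 8 replicates = 64 LC-MS analyses over 33 integrated
  fractions.

# Spot filtering and normalization

Spots flagged bad at scanning, and all non-experimental spot classes, are
removed first. The intensity filter discards spots whose
background-subtracted median signal is too close to background in **both**
channels. The source description of the threshold ("below 60% + 2 SD of the
overall background") is ambiguous; the package's default reading is

$$\text{fail channel } c \iff (F_c - B_c) < 0.6\,(\overline{B_c} + 2\,
\mathrm{SD}(B_c)),$$

with the mean and SD taken per array and channel over *all* printed spots
before any removal (control spots deliberately included, since blanks and
buffer spots are printed to measure background). The alternative
$\,(F_c-B_c) < \overline{B_c}+2\,\mathrm{SD}(B_c)\,$ is available as
`bg_rule = "mean_plus_2sd"`; it is never weaker than the default.

Global normalization is per-array mean-centering of the log-ratios: the
single-factor normalization appropriate for ratio data, and exactly the
transformation that stage 1 of the model performs. It is idempotent, and it
removes any additive per-array dye bias exactly. Its known cost is that it
assumes differential expression is sparse or symmetric: the array mean
includes the mean planted effect, so asymmetric mass up-regulation would
bias ratios downward. The synthetic generator therefore assigns planted
effect signs in balanced pairs by default (`balance_signs = TRUE`) — that is
the condition under which noise-free recovery is exact, and a green recovery
test establishes correctness *under that condition*, not robustness to
grossly asymmetric regulation.

Duplicated probes are collapsed by the arithmetic mean of their log-ratios
(the analysis scale), and a Box-Cox profile-likelihood diagnostic
(`boxcox_symmetry()`) reproduces the symmetry check that motivates the log
transform: lambda is profiled on a grid over $[-2, 2]$ in steps of 0.05,
with a 95% likelihood-ratio interval; "log" is recommended when 0 is in the
interval (winning ties against "identity").

# The two-stage mixed linear model

Stage 1 removes array-level variability:
$\log_2(\mathrm{Cy3}/\mathrm{Cy5}) = \beta_0 + \beta_1 M_{Array} + b_0 +
\varepsilon$. With one fixed effect per array the fitted array effect is the
array's mean log-ratio, so stage 1 is per-array centering; the between-array
variance is reported as the stage-1 random component. (The original
description includes a random intercept $b_0$ whose grouping it never
states; at array-level grouping it is confounded with the fixed array
effect, which is why centering is the whole of stage 1.)

Stage 2 models each unique probe's residuals:
$$e = \beta_{\iota 0} + \beta_{\iota 1}\,\mathrm{Trt} + \beta_{\iota 2}\,
\mathrm{Time} + \beta_{\iota 3}\,\mathrm{Trt{\times}Time} + b_{i0} +
\varepsilon^*.$$

Design decisions, and why:

* **Time is a 3-level factor**, not a slope: the model's deliverable is the
  six expected differential-expression values $Y_{ID,Trt\times Time}$ (2
  treatments x 3 times), which presuppose per-time cell means.
* **The random intercept groups biological replicate pairs**
  (`run:replicate`). Each array is a treatment-control pair; the replicate
  pair is the repeated unit that spans all six design cells. Run-level
  grouping is available (`grouping = "run"`).
* **Balanced probes use a closed form.** A probe observed once in every
  (replicate pair x cell) slot forms a balanced randomized complete block
  design, whose REML solution is the classical ANOVA decomposition: cell
  means are sample means, $\hat\sigma^2 = MS_E$ with
  $(n_{cells}-1)(n_{blocks}-1)$ degrees of freedom, and
  $\hat\sigma_b^2 = \max(0, (MS_{block}-MS_E)/n_{cells})$. This path is
  vectorized across probes, which is what makes the 500-replicate null
  calibration affordable. In the balanced case the fixed-effect estimates
  coincide with ordinary least squares for any variance ratio, so the
  documented mixed-equals-OLS-at-zero-variance property holds identically.
* **Unbalanced probes use `nlme::lme`** with the same formula and marginal
  F-tests; fits that fail fall back to OLS with type-II model comparisons,
  and the route taken is recorded per probe (`method`). Factors observed at
  one level are reported `NA` (untestable), never 0 or 1.
* **Per-cell tests are one-sample t-tests** of each cell's observations
  against zero (observations within a cell are iid with variance
  $\sigma_b^2+\sigma^2$), kept identical across fitting routes so that the
  choice of mixed-model engine cannot change a cell call.

## Multiplicity

Two layers are deliberately separate, because they answer different
questions:

* **Within a probe**, the cell-mean tests (and, via `tukey_contrasts()`,
  all 15 pairwise cell contrasts) are adjusted with the Tukey-Kramer
  studentized-range procedure; for a mean-versus-zero test with $k$
  populated cells the adjusted p-value is
  $P(Q_{k,\nu} > \sqrt{2}\,|t|)$. With a single comparison the adjustment
  is the identity, and adjusted values are never below raw ones.
* **Across probes**, the Trt x Time interaction F-test p-values are screened
  with the Benjamini-Hochberg step-up procedure at $\alpha = 0.05$. The FDR
  estimator behind the original screen is unstated; BH is the standard
  choice and is implemented directly (step-up over sorted p-values) with a
  brute-force oracle in the tests.

Headline per-treatment/time counts use the raw per-cell p-value at
p < 0.001, split by sign into induced and suppressed, with cross-treatment
overlaps per time point (`count_de()`).

# Clustering

The FDR-screened probes' complete 6-vectors (probes with any empty design
cell are excluded, with the excluded count reported) are clustered with
Ward's minimum-variance agglomeration on Euclidean distances
(`hclust(method = "ward.D2")`, heights $\sqrt{2\,\Delta SSE}$). The
"standardized covariance coefficients" of the original description admit two
readings, both implemented behind one switch and neither asserted as
authoritative: `standardize = "zscore"` (default) z-scores each design-cell
column against its pooled mean/SD; `"pca"` replaces vectors by
covariance-based principal-component scores. Candidate cut levels 3, 6, 9
and 12 are always reported with their relative merge-height gaps as a
stability readout, and k = 6 is the default cut.

Treatment-level (Eisen-style) clustering supports Pearson distance
$1 - r \in [0, 2]$ or a covariance embedding
$\sqrt{c_{ii}+c_{jj}-2c_{ij}}$, under single, complete, average (default)
or Ward linkage — the eight combinations that were compared historically.
`variance_scree()` gives the covariance eigenvalue scree and the smallest
component count reaching a target cumulative variance fraction (default
85%).

# Metabolite analysis

Raw XIC peak areas are adjusted for sample dry mass and for the
nearest-eluting internal standard (alkyl 4-hydroxybenzoates; ties break
toward the earlier-eluting standard) and then normalized to 100. "Normalized
to 100" is read as per-fraction maximum = 100 (`scale = "fraction_max"`),
which preserves between-sample contrasts within a fraction; the per-sample
total = 100 reading is available but mixes fractions of different ionization
efficiency. Normalization is scale-invariant per fraction, so the choice of
area units cannot matter.

Fractions detected in at least 90% of samples (detection floor: area > 0,
configurable) are **continuous** and fitted with
$$\log_2(\mathrm{Fraction}) = \beta_0 + \beta_1\mathrm{Exp} +
\beta_2\mathrm{Trt} + \beta_3\mathrm{TC} + \beta_4\mathrm{Trt{\times}TC}
+ b_0 + \varepsilon,$$
with the random intercept grouping replicate pools (`run:replicate`; the
original grouping is unstated) and OLS fallback recorded as in stage 2.
Condition-restricted fractions (camalexin appears only in pathogen-treated
tissue) are **dichotomous**: summarized as presence counts per condition
and never modeled — there are not enough observations to support a model,
and the package deliberately refuses rather than fabricating a fit.

# Bioassay computations

`cfu_per_cm2()` back-calculates bacterial density from plate counts through
dilution, plating fraction and leaf-disk area (default 6.25 mm cork borer).
`relative_expression()` implements
$\Delta C_T = C_T(\mathit{PR1}) - C_T(\mathit{18S})$ and fold change
$2^{-\Delta\Delta C_T}$. The two-group significance test is Welch's t-test,
explicitly an implementation stand-in since the original test is unnamed;
downstream CFU statistics use $\log_{10}(\mathrm{CFU}+1)$ to accommodate
zero counts.

# The synthetic-data generator

The generator is first-class, tested code: every downstream stage is
validated against its planted truth. Channel intensities are built on the
log2 scale — probe baseline ($\sim N(10, 1)$, i.e. median signal around
1000 intensity units), array effect (SD 0.3), constant Cy3 dye bias (0.3),
plus on the treated channel the true cell mean and a replicate-pair random
intercept (SD 0.15) — then exponentiated, with a per-spot additive
background ($N(100, 20)$, truncated at zero) recorded as the background
median. Residual log-ratio noise has SD 0.3, split equally between channels.
Control spots are signal-free except spikes. Experimental spots are flagged
bad with probability 0.02. The magnitudes are package choices — the source
reports none — selected once to resemble a clean two-color scan
(signal-to-background ~10:1, replicate CV ~20%) and not revisited;
`effect_size = 1.5` log2 units is a typical strong stress response. The
metabolite generator mirrors its design (64 analyses, 33 fractions,
residual log2 SD 0.35 ~ 25% CV, planted TC effect 2 log2 units) and
constructs raw areas as concentration x mass x nearest-standard area, so
the documented normalization inverts the nuisance factors exactly.

What the generator does *not* emulate — and what green tests therefore do
not establish — includes spatial artifacts and print-tip effects, dye-swap
designs (the original used none), intensity-dependent (loess-type) dye
bias, heavy-tailed noise, and correlated probe families beyond the 26
explicit duplicates.

# Numerical and degenerate-input choices

* Spot intensities are kept continuous (no integer rounding) so the
  noise-free recovery contract can hold to machine precision.
* Arrays with fewer than 10 usable spots are excluded with a warning;
  spots with non-positive background-subtracted signal in either channel
  are dropped with a logged reason (a log cannot be taken).
* Variance-component estimates are truncated at zero; 0/0 F statistics on
  constant data propagate as `NaN` and are never converted to significance.
* BH with an empty p-vector selects nothing; `tukey_contrasts()` requires
  at least two groups and one residual degree of freedom.
* Ward merge heights are monotone by construction; all-identical vectors
  yield a degenerate tree which is flagged rather than an error.

# Known limitations

The headline counts of the original dataset (771 FDR probes, 769 complete
vectors, cross-treatment overlaps 84/287/203) depend on that specific
60-array dataset, which this package can ingest through the same
`SpotRecord` model but does not ship; the configuration switches needed to
bracket those numbers (threshold rule, grouping, alpha, count threshold)
are all exposed. Dichotomous metabolites get no inferential treatment by
design. The pipeline is desk-scale and single-threaded.
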