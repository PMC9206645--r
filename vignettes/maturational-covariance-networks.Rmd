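---
title: "Maturational covariance networks: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maturational covariance networks: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnkit)
```

# The model

A maturational covariance network (MCN) is a group-level graph over brain
regions whose edge weights are *across-subject* correlations of regional
growth trajectories.  If infants who grow region *i* quickly also grow
region *j* quickly, the two regions are "maturationally coupled" —
development is synchronized at the population level.  Note what this is
not: it is not a within-subject connectivity measure, and a single group
yields a single matrix, so all inference is about groups, not individuals.

The pipeline is:

1. **Trajectory.** For each subject and region,
   $\mathrm{rate} = \frac{(v_2 - v_1)/v_1}{a_2 - a_1}$ — the volume change
   between the two scans, normalized on the first-scan volume, per week of
   inter-scan interval.  Normalizing on $v_1$ makes regions of different
   sizes comparable; dividing by the interval absorbs differences in scan
   timing.
2. **Covariate adjustment.** Per region, the rate is regressed (OLS) on
   gender, total brain volume, gestational age at birth, both scan ages,
   intraventricular hemorrhage, surgeries, pre- and postnatal
   corticosteroids and days of morphine.  The *externally studentized*
   residuals $t_i = e_i / (s_{(-i)}\sqrt{1 - h_{ii}})$ are carried forward.
3. **Association.** Per group, the matrix of Pearson correlations between
   regions' studentized trajectories, zero diagonal, plus the Fisher
   transform $z = \operatorname{atanh}(r)$.
4. **Network-level test.** Both groups' matrices are thresholded at the
   same density $K$ (the top $m = \mathrm{round}(K \cdot 496)$ of the 496
   edges by signed $z$) and binarized; retained edges are counted in six
   blocks (within-SN/DMN/ECN, SN–DMN, SN–ECN, DMN–ECN).  The observed
   $\Delta = \text{count}_{\text{high}} - \text{count}_{\text{low}}$ per
   block is referred to a permutation distribution obtained by reshuffling
   group labels (preserving group sizes) and recomputing the entire
   pipeline from the association matrices on.  Two-tailed
   $p = (1 + \#\{|\Delta_{\pi}| \ge |\Delta_{\mathrm{obs}}|\})/(1 + B)$,
   BH-FDR across the six blocks within each density.
5. **Edge-level test.** Per edge, the independent-samples Fisher statistic
   $Z = (\operatorname{atanh} r_h - \operatorname{atanh} r_l) /
   \sqrt{1/(n_h-3) + 1/(n_l-3)}$, two-sided normal $p$, BH-FDR across
   included edges; edges with $|r| < 0.10$ in both groups are excluded as
   spurious before transformation.

Assumptions worth keeping in view: growth is treated as linear between the
two scans (only two timepoints exist, so nothing richer is identifiable);
covariate effects on rates are linear and additive; Pearson correlation is
the coupling measure, so only linear across-subject dependence counts; and
the equal-density constraint means each group's network has exactly $m$
edges, so the six $\Delta$ values always sum to zero — the blocks compete
for a fixed edge budget and the six tests are negatively dependent (BH
remains valid under this kind of dependence).

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| density sweep | 0.10–0.30, step 0.01 | fraction of 496 edges | below 0.10 networks fragment; above 0.30 covariance patterns become increasingly random and non-biological |
| reporting density | 0.20 | fraction | a single density for headline numbers, robustness judged across the sweep |
| permutations | 5000 | draws | Monte-Carlo SE of a p near 0.05 is about 0.003 |
| spurious-correlation cut | 0.10 | \|r\| | correlations this small at n = 90 are dominated by sampling noise |
| stress SD convention | population (divisor n) | — | the score is a cohort-relative z-value, not an estimator of a superpopulation SD; sample convention available |

# What the synthetic generator emulates

`simulate_cohort()` draws, per subject: covariates on the scales of an
extremely-preterm NICU cohort (birth gestational age normal 26.64 ± 0.99
truncated to [24, 28) weeks; scans near 30.0 ± 0.97 and 41.0 ± 0.90
post-menstrual weeks; 43.3% female; realistic rates of hemorrhage,
surgeries, corticosteroids, morphine); a latent per-region growth-rate
vector from a group-specific multivariate normal whose correlation matrix
has constant blocks defined by the network partition; linear covariate
effects added to the rates; volumes constructed exactly as
$v_2 = v_1(1 + \mathrm{rate}\cdot\Delta\text{weeks})$; and
invasive-procedure counts Poisson-distributed with a per-day rate that is
higher in the high-stress group, accumulated over the simulated NICU stay,
so the standardized stress score of the high group stochastically dominates
the low group and a median split recovers the true labels almost surely at
n = 180.

The default block-correlation targets encode the qualitative effect
pattern the pipeline is designed to detect — high-stress group: within-SN
0.25 → 0.55 (+0.3), within-DMN 0.55 → 0.25 (−0.3), SN–DMN 0.35 → 0.15
(−0.2), all other blocks equal across groups (ECN 0.40; SN–ECN and
DMN–ECN 0.20).  The growth-rate scale (mean 0.06/week, SD 0.015) is a
scale-plausible placeholder for rapid third-trimester growth; no empirical
rate distribution was available to match, and only the correlation
structure, not the rate scale, drives the analysis.

What the generator does *not* emulate: measurement noise in segmentation
(rates are observed exactly); non-Gaussian or heavy-tailed growth;
nonlinear covariate effects; missing data; spatial autocorrelation between
neighbouring regions beyond the block structure; and any real anatomical
asymmetry.  Passing tests therefore demonstrate that the pipeline's
statistics behave as designed under its own model assumptions — they say
nothing about segmentation quality or about whether real cohorts satisfy
those assumptions.

Arbitrary per-block targets need not form a positive semi-definite matrix;
`build_block_correlation()` repairs infeasible target sets by eigenvalue
clipping (negative eigenvalues floored at 1e-8, reconstruction,
re-standardization to unit diagonal) and reports the largest entry shift;
a shift above 0.05 triggers a warning.  The defaults are feasible without
repair.

# Numerical choices

* **Thresholding ranks signed z, descending.**  "Strongest" edges are the
  largest positive couplings, the standard convention in structural
  covariance work; an absolute-value mode exists
  (`rank_by = "absolute"`).  Ranking on r or z is equivalent (atanh is
  monotone), which the permutation fast path exploits.
* **Ties** in edge weights are broken by lexicographic ROI-pair order, and
  ties in stress scores by (score, subject id), so every run is exactly
  reproducible; `m = floor(K·E + 0.5)` rounds half up.
* **Perfect correlations** (possible in tiny synthetic fixtures) are
  clipped to ±(1 − 1e−7) before atanh with a warning; at realistic n this
  never triggers.
* **Externally studentized residuals** are the default adjustment — the
  strict meaning of "studentized" — with internal standardization as an
  option; rates are residualized (not volumes), since the trajectory is
  the quantity whose covariance defines the network, with a
  volumes-first switch (`adjust = "volumes"`) for sensitivity analysis.
* **Stress weighting** is division: procedures per NICU day.  Weighting a
  cumulative count "on" stay duration admits a regression-adjustment
  reading, but rate-per-day is the standard one; the scoring function is
  small and separable if a user needs the alternative.
* **Degenerate inputs** fail loudly with the offending subject or region
  named: non-positive volumes, non-increasing scan ages, zero-variance
  trajectories, rank-deficient covariate designs, leverage-one
  observations, zero or negative NICU days, constant stress scores.
* **FDR family** is the six block comparisons within one density (sweep
  densities are a robustness display, not independent discoveries); at the
  edge level the family is all included edges of one comparison.
* **zero-mean split** assigns a score of exactly 0 to the high group
  (< 0 is low); group splits require at least two subjects per group, and
  downstream network construction at least four.
* **Spurious-edge filter** excludes an edge only when \|r\| < 0.10 in
  *both* groups: an edge strong in one group and absent in the other is
  precisely a decoupling signal and must not be discarded.  The filter is
  on \|r\|; filtering signed r would silently drop strong negative
  correlations.  An "either-group" mode exists behind a flag.

# Test and simulation scales

The test suite validates the permutation machinery against exhaustive
enumeration on a 4+4-subject, 6-region cohort (all 70 label splits);
calibrates type-I error on 500 replicate null cohorts of 45 subjects per
group at 200 permutations each; and measures recovery of the planted
effect pattern on 100 replicate 90/90 cohorts at 200 permutations.  The
acceptance script uses 2000 permutations for the main fit and 200/100
replicates for calibration/recovery.  These sizes give Monte-Carlo
standard errors comfortably below the margins being checked while keeping
a full run in minutes on one CPU.

# Known limitations

* **Discreteness of the count statistic.**  $\Delta$ is an integer, and
  when a block's retained count barely varies under permutation (which
  happens when within- and between-block correlations are far apart, so
  the density threshold falls in a gap), its null distribution is heavily
  tied and the exact add-one permutation p becomes conservative —
  uncorrected rejection rates at $\alpha = 0.05$ can drop to ~0.02 for
  such blocks.  Under the default study conditions all six blocks are
  calibrated (0.038–0.054 measured over 500 null replicates), but users
  planting strongly separated structures should expect conservatism, not
  inflation.
* **Between-network Δ magnitudes depend on baseline competition.**
  Because every network retains exactly m edges, the visible size of a
  planted between-block change depends on where that block's correlations
  sit relative to the retention threshold, not only on the planted
  difference; the planted −0.2 SN–DMN effect yields a modest (though
  reliably negative and significant) Δ under the defaults.
* **Group-averaged networks** admit no subject-level inference and no
  estimate of inter-individual variability; dichotomizing a continuous
  stress score costs power by construction.
* The edge-level Fisher Z treats the two groups' correlations as
  independent estimates and inherits the usual fragility of
  correlation-difference tests at small n.
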