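# mcnkit

Maturational covariance network (MCN) analysis for longitudinal regional
brain volumes, with a focus on early-life stress in extremely preterm
infants.

## The problem

Infants born before 28 weeks of gestation spend the "third trimester" in a
neonatal intensive care unit, exposed to repeated invasive procedures (heel
lances, line insertions, ventilation, suctioning).  A way to ask whether
this early-life stress reshapes brain development is to look at
*maturational coupling*: how synchronized the growth trajectories of brain
regions are across subjects.  Two regions are maturationally coupled when
infants with fast growth in one tend to show fast growth in the other.

`mcnkit` implements the full group-comparison pipeline over 32 regional
gray-matter volumes (16 per hemisphere) covering key nodes of three
canonical large-scale networks — the salience network (SN), default mode
network (DMN) and executive control network (ECN) — measured at two scans
(around 30 and 41 post-menstrual weeks):

1. **Stress scoring** — cumulative invasive-procedure count weighted by
   NICU-stay duration (procedures per day), standardized over the cohort;
   groups split by median, zero-mean or tertiles.
2. **Growth rates** — per region, `rate = ((v2 − v1)/v1) / (age2 − age1)`
   in fractional change per week.
3. **Covariate adjustment** — per region, OLS regression of the rate on
   gender, total brain volume, gestational age, scan ages,
   intraventricular hemorrhage, surgeries, pre/postnatal corticosteroids
   and days of morphine; externally studentized residuals carried forward.
4. **MCN construction** — per group, the 32×32 matrix of across-subject
   Pearson correlations `r_ij` between regions' studentized trajectories
   (zero diagonal), plus the Fisher transform `z = atanh(r)`.
5. **Network-level inference** — both groups' matrices thresholded at equal
   density K (top `m = round(K·496)` edges by signed z) and binarized;
   retained edges counted per block (within-SN/DMN/ECN and the three
   between-network blocks); the observed count difference Δ = high − low
   tested against 5000 label permutations (two-tailed percentile p with
   add-one smoothing, Benjamini–Hochberg FDR across the six blocks per
   density); densities swept over 0.10 ≤ K ≤ 0.30 and reported at K = 0.20.
6. **Edge-level inference** — per edge,
   `Z = (atanh(r_high) − atanh(r_low)) / sqrt(1/(n_high−3) + 1/(n_low−3))`
   after removing spurious correlations (|r| < 0.10 in both groups), with
   BH-FDR across included edges.

Because clinical MRI cohorts of this kind are not publicly shareable, the
package includes a synthetic-cohort generator
(`sim_config()`/`simulate_cohort()`) that reproduces the statistical
structure the analysis assumes — group-dependent block-correlated growth
rates, covariate confounding, group-consistent stress exposure — so every
stage is testable end to end.

## Worked example

```r
library(mcnkit)

sim <- simulate_cohort(sim_config(n_per_group = 90, seed = 11))
fit <- mcn_compare(sim$cohort, stress = sim$stress, n_perm = 2000, seed = 11)
fit
```

```
Maturational covariance network comparison
  groups: low (n = 90) vs high (n = 90); 2000 permutations
  coupling differences (high - low) at density K = 0.20:
      block delta      p      q
  within-SN    66 0.0005 0.0010
 within-DMN   -59 0.0005 0.0010
 within-ECN     5 0.6110 0.7330
     SN-DMN   -22 0.0005 0.0010
     SN-ECN    -1 0.8490 0.8490
    DMN-ECN    11 0.0455 0.0682
```

The generator's default conditions plant a high-stress group with stronger
within-SN coupling (+0.3 on the correlation scale), weaker within-DMN
coupling (−0.3) and weaker SN–DMN cross-coupling (−0.2).  The fit recovers
exactly that signature: at 20% density the high-stress network retains 66
more within-SN edges and 59 fewer within-DMN edges than the low-stress
network, with SN–DMN decoupling (Δ = −22), all with permutation p below
0.001; the unplanted ECN blocks stay near zero.  `summary(fit)` adds
sweep-robustness columns (fraction of densities agreeing in sign with the
reported one) and the edge-level tally; `plot(fit)` draws Δ against density
per block with the permutation 95% band; `coef(fit)` returns the six Δ
values.

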