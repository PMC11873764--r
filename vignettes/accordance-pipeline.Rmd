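---
title: "Accordance-based longitudinal connectome analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accordance-based longitudinal connectome analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accordnet)
```

## The analysis problem

Resting-state fMRI studies of preterm infants ask how the coupling between
large-scale brain networks matures between a scan at ~33 weeks gestational
age and a second scan at term-equivalent age (~40 weeks), and whether an
environmental enrichment delivered between the scans — here a music
intervention during neonatal intensive care — modulates that maturation.
The raw material per subject-session is a set of N network time courses
(one BOLD signal per resting-state network, extracted upstream by group
ICA) of T volumes, together with the six rigid-body realignment parameters
of each volume. `accordnet` implements the downstream analysis as a tested
pipeline:

1. **Motion scrubbing.** Volumes corrupted by head motion are censored
   using framewise displacement (FD) and DVARS criteria, with neighbor
   removal and a retention-based inclusion rule.
2. **Connectome estimation.** Each subject-session yields an N×N matrix of
   *accordance*, a coactivation/codeactivation coupling statistic computed
   on threshold-gated standardized signals.
3. **Maturating circuitry of interest (COI).** Edge-wise paired t-tests
   (session 2 vs session 1 across all subjects) with Benjamini–Hochberg
   FDR control select the connections that mature significantly.
4. **Intervention effect.** On the COI, within-group paired tests are
   converted to z-scores via the normal quantile function and the group
   difference is standardized by √2; edges with `z_diff ≥ 1.3`
   (one-sided p ≤ 0.1) are called significant.

A synthetic cohort generator with planted ground truth makes every stage
testable end to end.

## The accordance statistic

Each network signal is standardized (sample mean 0, sample SD 1 with
denominator n−1) and gated at a symmetric threshold pair (+u, −u), where
u is the standard-normal quantile of 0.8 (u ≈ 0.8416): the suprathreshold
part x⁺ keeps values ≥ u, the subthreshold part x⁻ keeps values ≤ −u, and
the thresholded energy is σ = √(⟨x⁺,x⁺⟩ + ⟨x⁻,x⁻⟩). For two networks i, j

$$a_{ij} \;=\; \frac{\langle x_i^+, x_j^+\rangle + \langle x_i^-, x_j^-\rangle}{\sigma_i\,\sigma_j},
\qquad
d_{ij} \;=\; -\,\frac{\langle x_i^+, x_j^-\rangle + \langle x_i^-, x_j^+\rangle}{\sigma_i\,\sigma_j}.$$

Accordance counts coherent activation and deactivation; discordance counts
anti-coupled exceedances. Both are symmetric and bounded in [0, 1]
(same-sign inner products plus Cauchy–Schwarz), and self-accordance is
exactly 1 because of the per-signal energy normalization — that choice is
what puts all subjects' matrices on a comparable scale. The algebra here
is the magnitude-retaining form (thresholded samples keep their values); a
binary ±1 variant is available via
`accordance_params(variant = "binary")`. Two further conventions are
deliberate:

* the lower gate is fixed at −u, i.e. activation and deactivation are
  treated symmetrically on the standardized signal;
* signals are standardized and gated *after* scrubbing, so censored
  volumes influence neither the normalization nor the threshold crossings.

Edges involving a network that never crosses its threshold are reported as
undefined (`NA`) and excluded listwise from downstream statistics rather
than imputed as zero — imputation would fabricate coupling. Note that
accordance of two *independent* signals is not centered at zero: its null
expectation is ≈ 0.18 at these settings (the statistic is non-negative by
construction). All inference is therefore paired or between-group, never
against zero.

## Motion scrubbing

FD is the Power-style sum of absolute backward differences of the six
realignment parameters, with rotations converted to arc length on a
50 mm sphere. DVARS is the root-mean-square (across networks) backward
difference of the raw-scale signal, expressed as a percent of the grand
mean signal; it is a network-level stand-in for the voxel-level quantity,
which is why the pipeline consumes *un-demeaned* time courses. The first
volume of both traces is defined 0 (no predecessor).

A volume is flagged when FD > 0.5 mm **or** DVARS > 3% (strict
comparisons, reading "higher than" literally); for each flagged volume the
one preceding and the two following volumes are removed as well, and
overlapping windows are unioned. A session is included when at least 50%
of volumes remain (inclusive comparison — retaining exactly half
suffices). A subject losing either session also loses its longitudinal
pair and drops from all paired stages; the QC report records each
exclusion.

```{r qc-demo}
tc <- matrix(1000 + rnorm(300, sd = 10), 100, 3)
tc[40, ] <- tc[40, ] + 60   # 6% signal excursion
motion <- matrix(0, 100, 6)
motion[40:100, 1] <- 0.8    # 0.8 mm translation jump
s <- scrub_session(tc, motion)
which(!s$qc$keep)           # the flagged volume and its 1-before/2-after window
s$retained_fraction
```

## The longitudinal statistics

**COI definition.** For each edge, the per-subject accordance differences
d_s = a_s(t40) − a_s(t33) enter a classical paired t-test
(t = d̄/(sd(d)/√n), df = n−1). The test is two-sided by default — the
direction of maturation is read off the sign of the edge-weight difference
(EWD = d̄) afterwards — with a one-sided-increase mode available. Raw
p-values are adjusted by the Benjamini–Hochberg step-up rule over the full
edge family (m = N(N−1)/2, i.e. 55 edges for 11 networks), and the COI is
the set with adjusted p ≤ 0.05. `bh_fdr()` also accepts a family size m
larger than the number of supplied p-values, treating the supplied values
as the smallest of m tests; that convention is what lets the adjusted
values of a published table be recomputed from only its printed
(significant) rows, and it is validated against the shipped
`reference_coi_table()` to four decimals.

**Intervention effect.** Within each group, each COI edge gets a
one-sided-increase paired t-test p-value — one-sided because the
hypothesis is specifically *enhanced* maturation under the intervention.
The normal quantile transform z = Φ⁻¹(1 − p) makes each group's statistic
exactly standard normal under its null (p-values of an exact test are
uniform), and for independent groups the variance-sum law gives
Var(Z_PM − Z_PC) = 2, so

$$z_{\text{diff}} = \frac{Z_{PM} - Z_{PC}}{\sqrt 2} \sim N(0, 1)
\quad\text{under the null.}$$

The covariance term is taken as zero by design (distinct infants in the
two groups). Significance uses z_diff ≥ 1.3 inclusively, the conventional
one-decimal rounding of the 90% normal quantile (1.2816). P-values are
clamped to [10⁻¹⁵, 1−10⁻¹⁵] (with a warning) before the quantile
transform so extreme within-group effects yield finite z-scores; the
clamp caps |z| near 7.94, far above any decision threshold in use.

## The synthetic cohort generator

No public per-subject data accompany this design, so the generator is the
package's test bed: it emulates a two-group (24 music / 19 control),
two-session cohort of 11 network time courses with 590 volumes at
TR = 0.7 s per session.

* **Signal model.** Each session is a stationary Gaussian AR(1) process
  per network (x_t = φx_{t−1} + √(1−φ²)ε_t, φ = 0.4 by default, a
  plausible autocorrelation at this TR) with instantaneous cross-network
  correlation set by a target correlation matrix; the stationary
  cross-correlation equals the target exactly, which is what makes
  moment-recovery tests sharp. Gaussianity is chosen deliberately:
  accordance on gated Gaussian signals has a tractable Monte-Carlo
  oracle. Signals are placed on a BOLD-like scale (mean 1000, SD 10,
  ~1% fluctuation) so that DVARS-as-percent is well defined.
* **Planted effects.** Session 1 uses compound-symmetric baseline coupling
  of 0.2. At session 2, a 12-edge hub-structured set gains +0.15
  correlation in both groups (maturation), and one designated edge gains
  a further +0.15 in the music group only (the intervention effect; the
  edge lies inside the maturating set so it belongs to the COI). Every
  post-increment matrix is re-validated as positive semi-definite at
  configuration time; invalid configurations are rejected with the
  offending eigenvalue.
* **Motion artifacts.** Each volume (except the first, where FD and DVARS
  are defined 0) independently becomes a spike with probability 0.03. A
  spike adds a global signal offset of 60 units (6% of mean) that decays
  linearly over the next two volumes (60, 40, 20, 0), plus a persistent
  0.8 mm translation jump. The decay shape is chosen so the artifact
  produces exactly one suprathreshold DVARS excursion (the return steps
  are 2% each, below the 3% gate) and one FD excursion, and the whole
  artifact lies inside the 1-before/2-after censoring window — scrubbed
  data are artifact-free, so the generator provides recoverable ground
  truth rather than a corrupted cohort.
* **Seeds.** A master seed plus a counter-based per-subject-session
  derivation makes outputs byte-reproducible and independent of cohort
  size.

What the generator does **not** emulate: non-Gaussian BOLD features
(spectral structure beyond AR(1), physiological noise, hemodynamic
nonstationarity), spatially correlated motion effects that survive
censoring, ICA estimation error in the time courses, and between-subject
heterogeneity of coupling (all subjects in a group share the target
matrix). Passing recovery tests therefore demonstrates the pipeline's
statistical machinery under its stated model, not robustness to every
artifact of real infant fMRI.

## Numerical choices and problem sizes

* Sample (n−1) standard deviations throughout; threshold comparisons
  `>= u` / `<= -u` keep the gates symmetric and deterministic at ties.
* Undefined quantities are `NA` with explicit warnings, never silent
  zeros; degenerate paired differences (zero variance) yield an undefined
  t and can never enter the COI.
* Raw-p ties in reports are broken by sorting on region labels, so output
  tables are deterministic.
* Validation suites run at sizes chosen to balance Monte-Carlo resolution
  against runtime: the null calibration of z_diff uses 500 replicate
  cohorts at a reduced size (6 networks, 80 volumes, 6 subjects per
  group) — legitimate because the calibration is size-free (paired-t
  p-values are exactly uniform under the null at any n and T) — while
  planted-effect recovery runs at the full default conditions
  (43 subjects, 11 networks, 590 volumes) over 15 replicates.

## Known limitations

* DVARS is computed on network time courses, not voxel data; it
  approximates the voxel-level criterion the scrubbing convention was
  defined for.
* The accordance normalization is the package's declared algebra (energy
  normalization, symmetric gates); other formulations of the statistic
  exist in the literature.
* The exact family size m of a published table is an analysis choice; the
  default here is all N(N−1)/2 edges, configurable via
  `stats_config(m = ...)`.
* The intervention test assumes independent groups and exchangeable
  within-group pairing; covariate adjustment (sex, gestational age at
  birth) is out of scope.
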