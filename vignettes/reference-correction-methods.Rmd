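---
title: "Methods: model-based 13C reference correction for protein NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based 13C reference correction for protein NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftref)
```

## The problem

Protein NMR chemical shifts are reported in ppm relative to a reference
standard (DSS for proteins). When referencing is done incorrectly --
which is common in deposited data -- every shift of a nucleus type is
off by a single constant. For carbon, even errors of a few tenths of a
ppm degrade amino-acid typing, resonance assignment, and shift-based
secondary-structure analysis. The catch is circular: standard
re-referencing tools need assigned shifts (or a structure), while good
assignment needs correct referencing.

`shiftref` breaks the circle. It estimates the carbon referencing offset
from *unassigned* data: unordered (Cα, Cβ) chemical-shift pairs, one per
spin system, as produced by grouping an HN(CO)CACB-type peak list by
amide root. The only other inputs are the protein sequence and a 3-state
secondary-structure string (H/E/C, e.g. from a sequence-based
predictor). An assigned-mode variant refines the estimate once
assignments exist.

## The statistical model

For each of the 19 non-glycine residue types (cysteine split into
oxidized and reduced forms, giving 20 model classes) and each secondary
structure, the joint (Cα, Cβ) shift distribution is modelled as a
bivariate normal with mean $(\mu_\alpha, \mu_\beta)$ and covariance
matrix

$$\Sigma = \begin{pmatrix} sd_\alpha^2 & \mathrm{Cov}_{\alpha\beta} \\
\mathrm{Cov}_{\alpha\beta} & sd_\beta^2 \end{pmatrix},$$

60 bivariate models in all (plus three univariate glycine models, unused
by default -- see *Glycine* below). A spin system $v$ is scored against
class $(AA, SS)$ with the squared Mahalanobis distance
$\chi^* = (v-\mu)\,\Sigma^{-1}(v-\mu)^T$, which under the class model is
$\chi^2_2$-distributed, so $p = P(\chi^2_2 \ge \chi^*) = e^{-\chi^*/2}$
is a plausibility in $(0, 1]$ that equals 1 at the class mean. Because
unassigned pairs are unordered, both orderings are scored and the larger
plausibility kept per model; the two cysteine-state plausibilities are
summed into one cysteine class, giving 57 values per spin system.

Averaging the per-spin-system normalized plausibility vectors over a
dataset yields an estimated residue-type/secondary-structure composition
$Y'$ (length 57). The sequence and its secondary-structure string give
the true composition $Y$. A candidate referencing correction $c$ is
scored by subtracting $c$ from every carbon shift, recomputing $Y'(c)$,
and evaluating the weighted residual

$$R(c) = \sum_i \omega_i\, \lvert Y'_i(c) - (Y\,\Omega)_i \rvert ,$$

whose minimizer is the reported correction. Corrected shifts are
observed minus correction.

### Covariance-matrix variants

Six assembly rules for $\Sigma$ are supported; they differ in how much
secondary-structure specificity and covariance they use:

| variant | variances | off-diagonal |
|---|---|---|
| A | pooled across SS | 0 |
| B | SS-specific | 0 |
| C | pooled | pooled covariance |
| D | SS-specific | mean of the three SS covariances |
| E | SS-specific | SS-specific covariance |
| E_revised | SS-specific | SS-specific, re-estimated after quality filtering |

Pooling weights are the per-class $n-1$. E_revised is the default
recommendation: corpora assembled from multiple spectra per entry
contain entries whose Cα and Cβ come from different experiments, which
destroys the within-residue correlation and corrupts naive covariance
estimates.

### The prediction-overlap prior

The class ellipses overlap heavily, so the classifier systematically
leaks mass from narrow classes into broad ones: $Y'$ is a *blurred*
composition and comparing it with the crisp $Y$ is biased. Instead of
deconvolving $Y'$ (ill-posed), the package blurs $Y$ the same way: the
overlap matrix $\Omega$ has row $t$ equal to the average normalized
plausibility vector of class-$t$ data, so $Y\,\Omega$ is the composition
the classifier is *expected* to report for data of true composition $Y$.
$\Omega$ is row-stochastic; its diagonal $\omega$ (a class's
self-recovery) weights the residual so that the least-confusable classes
dominate. Rows index the true class and are normalized to sum 1 -- the
only orientation under which $Y\,\Omega$ conserves mass and mimics
prediction overlap; descriptions of this construction sometimes speak of
column normalization, which would not conserve mass under
right-multiplication, so the row convention is used and stated here
explicitly.

$\Omega$ is built from corpus records scored with the same
unordered-pair convention the engine uses on unknown data, which makes
the central self-consistency exact: data simulated from the models with
composition $Y$ yields $Y' \to Y\,\Omega$ as $n$ grows.

### Optimization

The default optimizer is a two-round grid search: 50 evenly spaced
candidates on $[-5, 5]$ ppm (raw value $M_1$), then 50 evenly spaced
candidates on $[M_1-1, M_1+1]$ (final value $M_2$), 100 proposals in
all, with ties broken toward the candidate of smallest absolute value.
Fifty points on a 10-ppm range gives a round-1 spacing of 10/49 ≈ 0.204
ppm and a round-2 spacing of 2/49 ≈ 0.041 ppm; stated increments of
0.2/0.04 would need 51 points, and the 50-candidate count is taken as
definitive. Quantization therefore contributes at most about half a
round-2 step to the error. Differential evolution over the same residual
is available (`optimizer = "de"`).

### Assigned mode

With assignments known, each row is scored only against its own class
model: the objective is the mean $\chi^*$ over usable rows (non-glycine,
both shifts present; cysteine rows take the better of the two
oxidation-state models), a smooth one-dimensional function minimized by
differential evolution (rand/1/bin, F = 0.8, CR = 0.9, population 40, 50
generations, seeded, bounds $[-10, 10]$ ppm). The objective is not
prescribed in closed form anywhere authoritative; the mean per-row
chi-square is this package's choice, selected because it is the exact
negative log-likelihood of the row set up to class-constant terms, and
is unbiased at the true offset for model-drawn data (verified by
simulation in the test-suite).

## Deriving the class statistics

`fit_shift_models()` derives all 63 class parameter sets from an
assigned corpus: sample means, standard deviations and covariances with
$n-1$ denominators.

**Cysteine splitting.** Corpus records rarely label cysteine oxidation
states, but the two states are ~13 ppm apart in Cβ. Per secondary
structure, K-means with $K = 2$ (raw ppm coordinates, Euclidean
distance, 10 restarts with a fixed seed) splits the records; the cluster
with the larger mean Cβ is labelled oxidized, since disulfide-bonded Cβ
sits near 41 ppm versus ~28 ppm for the reduced form. The label rule is
a convention this package fixes explicitly.

**Covariance refinement (E_revised).** Each corpus entry carries RMSDs
of its Cα and Cβ shifts against structure-predicted values. The
comparison statistic

$$Q = \left( \frac{\lvert r_\alpha - r_\beta \rvert}{\lvert r_\alpha
\rvert + \lvert r_\beta \rvert} \right)^{1/3} \in [0, 1]$$

is small when the two RMSDs agree (the signature of a single-experiment
entry); the cube root un-skews the ratio. Entries are sorted by $Q$ and
every observed value is tried as a cutoff (an exhaustive, deterministic
scan standing in for a loosely specified recursive search); for each
admissible split (both groups at least 10 entries) the correlation
between Cα and Cβ deviations *from class means* -- deviations, so that
records pool across classes -- is computed per group and the two
correlations compared with a Fisher r-to-z two-sample test. The split
with the smallest p-value wins, provided it is significant at
$\alpha = 0.01$; otherwise there is no evidence of a decorrelated
subgroup and all entries are kept (without the gate, some minimum-p
split would always be selected even in pure noise). Covariances -- and
only covariances -- are then recomputed from the selected entries.

## Peak grouping

An HN(CO)CACB peak list has two peaks per residue (one for glycine)
sharing an amide ¹H/¹⁵N root up to jitter. Grouping proceeds in three
steps.

1. **Registration.** Peaks belonging to one root are mutual nearest
   neighbours in the (h, n) plane, so the per-dimension medians of
   mutual-nearest-neighbour distances estimate the jitter scale;
   tolerances are 3× those medians (≈ 2.9 jitter-sd, since the median
   absolute pair difference is $0.674\sqrt{2}\,\sigma$), floored at
   0.001 ppm (¹H) and 0.01 ppm (¹⁵N).
2. **Clustering.** Connected components under the neighbour relation
   $(\Delta h/tol_h)^2 + (\Delta n/tol_n)^2 \le 9$ (3σ per dimension
   equivalent), minimum cluster size 1 so glycine singletons survive.
   Three-peak clusters keep their closest pair and return the extra
   peak; clusters of four or more mean coincident amide roots, where
   any pairing would be a guess, so all their peaks are flagged
   ambiguous and excluded.
3. **Iteration.** A first-pass singleton is either a glycine or one
   orphan of an over-jittered pair -- locally indistinguishable. Later
   rounds pool singletons and ungrouped extras, inflate the tolerances
   (re-estimated on the pool but capped at 2× per round), and accept
   only mutual-nearest-neighbour pairings within the cutoff, a stricter
   rule than first-pass clustering so that well-separated glycines are
   not forced together. Iteration stops when a round adds nothing
   (at most 5 rounds).

Two-peak groups become unordered carbon pairs; singletons (no Cβ) and
ambiguous peaks are excluded from the correction input.

## Synthetic data and the default parameter set

No corpus ships with the package. The built-in default models
(`default_shift_models()`) are assembled in code from field-typical
random-coil Cα/Cβ values plus standard secondary-structure offsets
(helix: Cα +2.8, Cβ −0.6; strand: Cα −1.6, Cβ +2.2 ppm), per-SS spreads
of 1.0–1.4 ppm, and a Cα/Cβ correlation of −0.3 for all classes except
oxidized cysteine (+0.3), mirroring the sign structure reported for
re-referenced corpora. They are synthetic, clearly labelled as such, and
serve two roles: a usable default and the generating truth for every
simulation in the test-suite, so that generator parameters are the
oracle for parameter-recovery checks.

The generators (`simulate_corpus()`, `simulate_spin_systems()`,
`simulate_assigned_table()`, `simulate_peak_list()`) emulate: per-class
bivariate-normal shifts, the two cysteine oxidation modes (drawn 50/50),
glycine Cα-only residues, a global additive ¹³C offset, uniform random
spin-system dropout, and ¹H/¹⁵N root jitter (defaults 0.004/0.04 ppm,
typical digital resolutions). Corpus entries can be partially
decorrelated with matching fabricated RMSD pairs, giving the covariance
refinement a recoverable planted structure. Amide roots are drawn
uniformly over (7.5–9.5, 105–130) ppm with a jitter-normalized minimum
spacing of 20; the clustering stage's linking reach is about 12
normalized units (3× tolerance inflation times the 3σ cutoff), so the
floor guarantees resolvable residues while leaving grouping difficulty
controllable.

What the simulations do *not* emulate: spectral artifacts and extra
peaks, carbon-dimension overlap, outliers from paramagnetic or ring
current or deuteration effects, non-Gaussian tails, and non-random
missingness. Passing simulation bounds therefore demonstrates
correctness of the implementation under its own model assumptions, not
performance on adversarial experimental data; the accompanying
experimental evidence for methods of this family comes from
re-referenced corpora, which this package deliberately does not
download.

## Numerical choices and degenerate inputs

* Per-spin-system plausibility vectors are normalized before averaging,
  so that the estimated composition is exactly comparable with
  $Y\,\Omega$; spin systems whose mass underflows in all 57 classes
  (far outliers) are dropped from the average.
* Ties in the grid search break toward the smallest absolute candidate.
* Datasets below 50% completeness (pairs vs non-glycine residues) warn
  but still fit.
* Fewer than 2 records in any class, an all-identical cysteine cloud,
  fewer than 4 peaks for registration, fewer than 5 usable assigned
  rows, and a singular class covariance all raise informative errors.
* All randomized components (K-means restarts, differential evolution,
  all generators) take explicit seeds and restore the caller's RNG
  state; identical inputs and seeds give bit-identical results.

## Glycine

Glycine has no Cβ, so its spin systems are singletons and its three
univariate Cα models overlap almost completely across strand and coil.
Including glycine predictors inflates the residual over the overlap
region and degrades the correction; the engine therefore works in the
57-class non-glycine space by default. The glycine models and the 3×3
glycine overlap block are implemented (`include_glycine = TRUE` in
`overlap_prior()`) for ablation studies.

## Problem sizes used in validation

The test-suite validates parameter recovery at 2,000 records per class
(median-level tolerances: means within 0.05 ppm, sds within 5%,
covariances within 10% -- at this corpus size the per-class standard
errors make per-class worst-case bounds meaningless), Monte-Carlo
consistency at 50,000 draws (2% relative), and correction accuracy on
100-replicate studies of 120-residue proteins with offsets uniform on
[−3, 3] ppm: the full method's central-90% error width, its 90th
percentile absolute error with and without 50% dropout, the assigned
variant, and the identity-prior ablation. `scripts/acceptance.R`
recomputes these five measures from scratch.

## Known limitations

* The default parameter set is synthetic; for production use derive
  statistics from a real re-referenced corpus with `fit_shift_models()`.
* A single correction is applied to both Cα and Cβ; per-nucleus offsets
  (misregistered spectra) are detected by the Q-statistic filtration at
  the corpus level but not corrected per dataset.
* Very small proteins or peptides carry too few spin systems for the
  composition residual to be sharp, and intrinsically disordered
  proteins violate the well-defined-structure assumption behind the
  class statistics.
* The registration step is a mutual-nearest-neighbour stand-in with the
  same interface as published registration algorithms, not a
  reimplementation of any of them.
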