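---
title: "Calibration methods for quantifying starch adulterants in peanut-skin powder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration methods for quantifying starch adulterants in peanut-skin powder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Peanut-skin powder, a polyphenol-rich medicinal material, is sometimes
bulked out with cheap starches. FT-NIR diffuse-reflectance spectroscopy
over 10,000–4,000 cm⁻¹ offers a fast, non-destructive way to quantify such
adulteration, but turning a 1,500-point absorbance vector into three
reliable numbers — sweet-potato starch % (`fA`), corn starch % (`fB`), and
total adulterant % (`fC = fA + fB`) — requires a multivariate calibration
pipeline: artifact-removing preprocessing, representative sample
partitioning, wavelength selection, and a regression model with tuned
hyperparameters. `nirstarch` implements that pipeline end to end, together
with a synthetic-spectra generator that supplies data with known ground
truth, so every stage can be tested quantitatively without access to
instrument data.

```{r, eval = FALSE}
library(nirstarch)
config <- pipeline_config(seed = 1)
res <- run_model_comparison(config)
res$report
```

## The synthetic data generator

The generator emulates the laboratory mixture design: fifteen total
adulteration levels (40, 36, 30, 24, 20, 16, 12, 8, 6, 4, 3, 2, 1, 0.5,
0 mass %), each prepared at one of five sweet-potato : corn ratios (1:1,
2:3, 3:2, 2:1, 1:3) with fifteen replicates, i.e. 225 samples. The ratio
assigned to each level is configurable; the default cycles the five ratios
but pins level 40 % to 2:3 and 36 % to 1:3, which puts corn starch at 24 %
and 27 % in two level groups and gives `fB` the long-tailed distribution
(most samples below 10 %) that the split diagnostics show as high-level
outliers.

Each pure component (peanut skin, sweet-potato starch, corn starch) is a
sum of Gaussian absorption bands. Band centers follow the near-infrared
assignments characteristic of these materials — peanut skin's
cis-double-bond fatty-acid marker near 4,700 cm⁻¹, its two strong C–H
overtone bands in 5,000–6,000 cm⁻¹ and a smooth weak response around
8,200–8,400 cm⁻¹; simpler, more symmetric O–H/C–H bands for the two
starches (sweet potato strongest near 4,300 and 6,850 cm⁻¹, corn near
5,000–5,300 and 8,000 cm⁻¹). Band widths and heights are synthetic
choices that produce plausible powder spectra; they are not measured
constants of real materials, and conclusions about real peanut skin should
not be read off them.

A sample with fractions `(fA, fB)` mixes linearly:

$$s(\nu) = \left(1 - \tfrac{f_C}{100}\right) e_{\text{peanut}}(\nu)
  + \tfrac{f_A}{100} e_{\text{sp}}(\nu) + \tfrac{f_B}{100} e_{\text{corn}}(\nu),$$

and the observed spectrum adds the artifacts that scatter-correction
preprocessing exists to remove:

$$x(\nu) = g\, s(\nu) + o + b\,(\nu - \bar\nu) + \varepsilon(\nu),$$

with per-sample gain $g \sim N(1, 0.05^2)$, offset
$o \sim N(0, 0.01^2)$, baseline slope $b \sim N(0, (10^{-6})^2)$ per
cm⁻¹, and white noise $\varepsilon \sim N(0, 0.002^2)$ absorbance units
per point. The gain and offset sds are typical of the sample-repacking
variability of powder diffuse reflectance; the white-noise sd corresponds
to a well-averaged FT-NIR scan. These defaults are deliberately strong
enough that raw-spectrum calibration is visibly worse than preprocessed
calibration, while leaving the headline prediction quality attainable.

The default grid has 1,557 points from 10,000 to 4,000 cm⁻¹ inclusive,
matching an 8 cm⁻¹-resolution FT-NIR export of that range.

What the generator does **not** emulate: Kubelka–Munk/radiative-transfer
nonlinearity of diffuse reflectance, instrument line-shape effects,
wavelength-correlated (pink) noise, band shifts with matrix composition,
and moisture variation. Linear mixing plus affine scatter is the
assumption the calibration methods themselves make, so passing tests shows
the pipeline is implemented correctly and behaves as designed under its
own model class — not that real peanut-skin spectra meet that model.

## Preprocessing

* **SNV** standardizes each spectrum to mean 0, sd 1 (sample sd,
  denominator $n-1$), removing offset and gain per spectrum.
* **MSC** regresses each spectrum on a reference by OLS over all
  wavelengths ($x = a + b\,r$) and corrects as $(x - a)/b$. The reference
  is the calibration-set mean; the same fitted reference transforms
  prediction-set spectra so no prediction information enters the
  transform.
* **SG** (Savitzky–Golay) fits a local polynomial (default window 11,
  order 2) in a moving window. Derivatives are taken with respect to
  wavenumber, so a second derivative has units of absorbance · cm²; the
  same window/order defaults are used for derivative spectra. At the
  spectrum edges the polynomial is fitted to the first (last) full window
  and evaluated at the edge positions; reflection padding was rejected
  because it fabricates curvature — and hence derivative artifacts — at
  band edges.

SNV and SG are stateless; within the pipeline all stateful fitting (MSC
reference, model training, wavelength selection, hyperparameter tuning)
uses calibration rows only.

## Sample partitioning

Kennard–Stone selects calibration samples by max–min Euclidean distance:
the two most distant samples seed the set, then each step adds the sample
farthest from the set. Ties break to the lowest index, which makes the
split fully deterministic. The default calibration fraction is 70 %
(rounded up), so 225 samples split 158/67. The distance space is the
spectra being modelled (preprocessed where preprocessing is applied; for
MSC the split is computed on the uncorrected spectra, since the reference
must be fitted on calibration rows that are only known after the split —
Kennard–Stone is unsupervised either way). `balance_test()` reports a
Welch two-sample t-test p-value comparing calibration and prediction
target distributions, plus Tukey-fence boxplot summaries; the Welch test
was chosen because the two groups have no reason to share a variance.
Note that Kennard–Stone deliberately concentrates extreme samples in the
calibration set, so on strongly designed data the two groups can differ
more than a random split would.

## CARS wavelength selection

Competitive adaptive reweighted sampling runs `N = 50` Monte-Carlo rounds
(configurable). Each round: draw 80 % of calibration samples without
replacement; fit a PLS model on the currently retained wavelengths; weight
each wavelength by its normalized absolute regression coefficient
$w_j = |b_j| / \sum_k |b_k|$; keep the top
$K_i = \max(2, \lceil r_i\,p \rceil)$ wavelengths, where the retention
ratio follows the exponentially decreasing schedule
$r_i = a e^{-k i}$ with $a = (p/2)^{1/(N-1)}$, $k = \ln(p/2)/(N-1)$ (all
$p$ kept at run 1, exactly 2 at run $N$); then resample $p$ times with
replacement in proportion to the weights and retain the distinct
survivors. Each round's subset is scored by 5-fold PLS RMSECV on the full
calibration set with a shared fold map; the subset with minimum RMSECV
wins, ties going to fewer wavelengths, then the earlier round. The
internal PLS latent-variable count is chosen once by cross-validation on
the full calibration set (capped at 10) and held fixed across rounds,
which stabilizes the weights and bounds runtime.

Because the weighted resampling draws $p$ times, the distinct-survivor
count tracks the forced schedule (after the characteristic ≈ 63 % drop at
run 1, when all weights are still nearly uniform); drawing only $K_i$
times instead would shrink the set by a further ≈ 0.63 factor every
round and collapse it to the floor of two variables within a dozen
rounds, independent of $N$.

## Calibration models

**PLSR.** NIPALS on mean-centered predictors and response (no variance
scaling; the spectra share units). The LV count is chosen by 5-fold
cross-validation over 1–20, smallest count at the minimal RMSECV. With a
single response NIPALS needs no inner iteration, and one decomposition
yields coefficient vectors for every candidate LV count. If the data run
out of rank the candidate range is capped with a warning.

**SVR.** ε-insensitive support vector regression with the RBF kernel
$K(x, z) = \exp(-g \lVert x - z\rVert^2)$, solved by libsvm. ε is fixed at
0.1 mass % (configurable): small against the 0–40 % target range, large
enough to keep the support set sparse. Spectra enter the kernel as-is —
the RBF kernel is translation-invariant, so column centering is a no-op,
and autoscaling is deliberately not applied so that `g` remains
comparable across preprocessing variants.

**Grid search.** Exhaustive 5-fold RMSECV over
$c \in 2^{-2}, 2^{-1.5}, \dots, 2^{10}$ and
$g \in 2^{-12}, \dots, 2^{2}$ (half-power-of-2 steps, the conventional
libsvm-style lattice). Ties break to smaller $c$, then smaller $g$.

**BKA.** The black-winged kite algorithm is a two-phase population
metaheuristic. In the attacking phase each kite perturbs its own position
with a step $n = 0.05\,e^{-2(t/T)^2}$ that shrinks over iterations (with
a 10 % chance of a larger sinusoidal excursion); in the migration phase
each kite moves relative to the current leader with Cauchy-distributed
steps, the heavy tails providing occasional long jumps out of local
minima. Moves are greedy (kept only if they improve the objective),
candidates are clamped to the search box, non-finite objective values are
rejected, and evaluations are cached. For SVR tuning the search runs in
$\log_2(c), \log_2(g)$ space (scale invariance) over
$c \in [0.01, 1024]$, $g \in [10^{-4}, 1]$, minimizing the same shared
5-fold RMSECV objective the grid uses, then refits on the full
calibration set at the optimum. Defaults are 20 kites and 20 iterations —
about 800 cached objective evaluations, a budget comparable to the
725-point grid and ample for a 2-D box. Since the equations above follow
the algorithm's published two-phase scheme but implementations vary in
detail, correctness is gated on behavior: bound feasibility, monotone
best-so-far trace, convergence on the sphere benchmark, and matching an
exhaustive grid on a discretized SVR objective.

## Metrics and reports

$R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ (the sum-of-squares
definition, not squared Pearson correlation — it can go negative for
models worse than the mean, which is the informative behavior for a
prediction set). RMSEC/RMSEP are root-mean-square errors on the
calibration and prediction sets in mass %; RMSECV pools out-of-fold
residuals, $\sqrt{\sum_i (y_i - \hat y_i^{(-\text{fold}(i))})^2 / n}$.
Folds are contiguous blocks after a seeded shuffle and are shared across
all models within one comparison, so RMSECV values are comparable between
models. Report rows carry the fitted parameters (`Lvs = k` for PLSR,
`c = …, g = …` for SVR) and the four headline metrics at 4 decimals.

## The two experiments

`run_preprocessing_comparison()` fits cross-validated PLSR per target on
raw, SNV, MSC and SG spectra (12 rows). `run_model_comparison()` runs the
full pipeline — SG smoothing, Kennard–Stone split, CARS per target
(selection is per target because each response keeps a different variable
set), then PLSR, grid-SVR and BKA-SVR on the selected wavelengths
(9 rows). `run_pipeline()` persists every stage artifact (spectra CSV,
split JSON with balance p-values, per-target CARS selections, both
tables, and a manifest with seed, configuration and versions) so a run
can be replayed or partially reused; staleness tracking between stages is
deliberately not implemented — the orchestration is purely functional,
which keeps determinism trivial to audit.

Every stochastic stage derives its seed deterministically from the single
pipeline seed; the same configuration reproduces every file byte for
byte.

## Numerical choices and degenerate inputs

* SNV refuses constant spectra (sd 0); MSC refuses a constant reference
  and spectra whose fitted slope is below 1e-12 in magnitude.
* The SG window must be odd, larger than the polynomial order, and
  smaller than the grid; derivative order may not exceed the polynomial
  order.
* NIPALS stops when the residual weight norm falls below 1e-12 (rank
  exhausted) and caps the LV search accordingly.
* CARS guards its retained set at a floor of two variables; cross-
  validated scoring uses `min(nLV, |subset|)` components.
* Ties: `which.min` everywhere (first/smallest index); Kennard–Stone
  seed-pair ties resolve row-major; grid-search ties prefer smaller `c`
  then `g`; CARS RMSECV ties prefer fewer variables, then earlier runs.
* A zero-support-vector SVR fit (all residuals inside the ε tube, e.g. a
  constant response) predicts the libsvm constant offset.

## Problem sizes used in the test suite

The packaged experiments run at the study scale: 225 samples × 1,557
points, 50 CARS runs, the full 725-point SVR grid, and the 20 × 20 BKA
budget, which completes in minutes on a single core. Unit tests exercise
the same code paths on smaller grids (tens of points, 2–4 replicates) so
the whole suite stays fast; the sizes are stated in each test and were
chosen as the smallest instances that still discriminate correct from
incorrect behavior (e.g. 100 × 300 with five planted informative
variables for selection recovery).

## Known limitations

* The generator's linear-mixing + affine-scatter model matches the
  assumptions of the calibration methods; agreement on synthetic data
  does not certify performance on real instrument spectra.
* Endmember band tables are illustrative, synthetic fixtures.
* The BKA search box caps `g` at 1; on targets whose cross-validated
  optimum lies above that (which can happen for very smooth, few-variable
  subsets) the grid search, whose lattice extends to `g = 4`, can reach a
  lower RMSECV than BKA. The box follows the convention that `g` of an
  RBF kernel on spectra of this dimensionality rarely exceeds 1; widening
  it is a one-argument change (`bka_config(g_bounds = …)`).
* One preprocessing dialect (wide CSV) only; vendor binary formats are
  out of scope.
* Single-response models only; the three targets are modelled
  independently.
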