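---
title: "Methods: simulated resting-state cohorts and conditional Granger causality between networks"
author: "rsnflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated resting-state cohorts and conditional Granger causality between networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `rsnflow`, the parameters that
matter, the numerical conventions, and the design decisions that were
genuinely open — in enough detail that a reader can judge what a passing
test suite does and does not establish about real data.

## 1. The generative model

A simulated subject is a time × voxel matrix

$$X = S\,M + E,$$

where the rows of $M$ (sources × voxels) are spatial loadings supported on
compact, pairwise-disjoint blob masks — four *network* sources (DAN, VAN,
AfN, VN) whose supports double as the identification templates, plus two
*nuisance* sources on their own disjoint blobs — and the columns of $S$ are
the source time courses. Network time courses follow a first-order vector
autoregression

$$x_t = A_{\mathrm{eff}}\,x_{t-1} + \varepsilon_t, \qquad
  \varepsilon_t \sim \mathcal N(0, \sigma^2 I),$$

with $\sigma = 1$ and, at the reference score, self-coupling $0.3$ and
directed couplings AfN→VN $= 0.45$, DAN→VAN $= 0.45$, AfN→VAN $= 0.35$,
DAN→VN $= 0.35$. Nuisance sources are independent AR(1) processes
($\phi = 0.3$). $E$ is i.i.d. Gaussian noise scaled so that the mean
in-mask temporal signal variance over the noise variance equals the
configured SNR (default 2 — a deliberate "workable but not clean" regime).

Two couplings are *modulated* by the subject's loneliness score $\ell$:

$$A_{\mathrm{eff}}[\mathrm{VN},\mathrm{AfN}]
  = \mathrm{clamp}\!\left(0.45 + s\,(\ell - \ell_0)\right),
  \qquad s = -0.025,\ \ell_0 = 55,$$

and likewise for DAN→VAN, with the clamp range $[0.05, 0.9]$. The high
group samples $\ell$ uniformly from 46–65, the low group from 20–27; the
other five scales (STAI, SDS, IRI_C, Trust, SSRS) are sampled independently
of the loneliness score and of group, so that they act as true nulls in the
correlation screen.

**Why slope −0.025 and reference 55.** The slope is the one generator
parameter that decides whether the planted brain–behavior relation is
*statistically recoverable* at the study's sample size (15 subjects per
group). A pre-implementation power calculation fixes it: the
least-squares estimate of a conditional influence term at $T = 250$ has
sampling noise of roughly $\mathrm{sd}(\hat F) \approx \sqrt{4F/T} \approx
0.05$, while the cross-subject spread induced by a slope $s$ over a
20-point score range is $\approx 0.7 \times 20|s|/\sqrt{12}$. Detecting
the correlation at $n = 15$ under Benjamini–Hochberg correction over the
12-test screen family requires the cross-subject signal to dominate,
i.e. $|s| \gtrsim 0.02$; $-0.025$ gives comfortable margin, while a slope
an order of magnitude shallower is undetectable at this $n$ in principle
(no implementation could recover it). The reference score 55 centers the
modulation inside the high group's range, so the high group stays in the
linear regime; the low group saturates at the 0.9 clamp, which both keeps
the process comfortably stationary and reproduces the qualitative finding
that within the *low* group the connectivity no longer tracks the score.

**What the generator does not emulate.** No hemodynamic response
convolution, no physiological or motion artifacts, no slice-timing
structure, no spatial nonstationarity of noise, no anatomical images, and
voxel counts three orders of magnitude below whole-brain resolution.
Passing tests therefore demonstrate the *statistical logic* of the chain —
identifiability, calibration, power at the study design — not robustness
to the messiness of real scans.

## 2. Preprocessing

The first 5 of 255 volumes are discarded (signal-equilibration
convention; TR = 2 s). Volumes are then smoothed with an isotropic
Gaussian kernel, FWHM 8 mm ($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per
axis, converted to voxels via the 3 mm voxel size), implemented as
separable 1-D convolutions with half-sample symmetric (reflective)
boundaries — a convention that preserves the per-volume sum exactly, which
the tests assert against a dense brute-force convolution.

## 3. Group spatial ICA

**Dimension.** The number of latent components is estimated by the
Wax–Kailath minimum description length criterion on the covariance
eigenspectrum, with $p$ the smaller and $N$ the larger data dimension.
Eigenvalues below numerical rank are excluded. Two caveats are built in:

- *Smoothed data*: spatial smoothing correlates neighboring voxels and
  violates the i.i.d.-sample assumption, inflating the estimate by an
  order of magnitude. The pipeline therefore estimates the dimension on
  the unsmoothed (discard-only) data; `estimateNdimMDLGrid()` offers the
  alternative stride-subsampling correction (sampling voxels at the
  smoothing scale) for cases where only smoothed data exist.
- A configurable cap (`maxK`, default 40) bounds the decomposition size.

**Reduction.** Subjects are concatenated along time, voxel columns are
centered (variance normalization is available but off by default — with
synthetic data of homogeneous scale it only discards information), and a
single-stage PCA retains the top-$k$ spatial principal directions. A
two-stage subject-then-group reduction is deliberately not used: at these
problem sizes the single eigendecomposition is exact and cheaper.

**Unmixing.** Symmetric fixed-point FastICA with the $\tanh$ contrast,
whitening included, seeded random-orthogonal initialization, tolerance
$10^{-6}$ on the rowwise fixed-point criterion, 500 iterations maximum.
Non-convergence is reported in the result object, never raised.
Spatial maps are the estimated sources (voxels are the ICA samples); group
time courses are the corresponding mixing columns mapped back through the
reduction.

**Sign convention.** ICA determines sources only up to sign and order.
Each component map is oriented to positive skewness, so focal sources load
positively — without this, template matching by the difference score fails
on sign-flipped components (order ambiguity is resolved only at template
matching, and all tests are invariant to it).

**Back-reconstruction.** Subject time courses are the subject's block of
the reduced data pushed through the group decomposition; subject maps are
the dual-regression coefficients of the subject's centered data on those
time courses, z-scored rowwise. "z-scoring" here is standardization of
the map (zero mean, unit variance across voxels) — the conventional
reading for ICA intensity maps; an `atanh` transform is undefined for
intensities beyond $\pm 1$ and is not what map displays use.

## 4. Network identification

Each z-scored map is scored against each binary template by
$\mathrm{mean}(z\ \mathrm{inside}) - \mathrm{mean}(z\ \mathrm{outside})$;
Pearson spatial correlation is computed alongside, and a warning is issued
when the two criteria disagree on a winner (the difference score is
primary). Assignment is greedy by descending score; when two templates
prefer the same component the higher-scoring template keeps it. Voxelwise
one-sample $t$ maps per group (and pooled-variance two-sample maps inside
the union of the groups' one-sample significance masks) are
Benjamini–Hochberg corrected at $q = 0.05$ over in-mask voxels;
zero-variance voxels get $p = 1$ and are logged.

## 5. Conditional Granger causality

For source X, target Y, and conditioning set Z (the remaining identified
networks — not all ICA components), the influence term is
$F_{X\to Y|Z} = \log(\hat\sigma^2_{\mathrm{restricted}} /
\hat\sigma^2_{\mathrm{full}})$, both residual variances taken from the
target's equation in least-squares VARs on the *identical* effective
sample (the first $m$ points are reserved as presample). This sample
convention is what makes the ratio a valid nested-model comparison; by
nesting, $F \ge 0$, and round-off below $-10^{-12}$ is clamped to zero.
The model order is selected by the Schwarz criterion
$\ln\det\hat\Sigma + (\ln T_{\mathrm{eff}}/T_{\mathrm{eff}})\,m d^2$ over
orders 1–5 fitted on a common presample; ties go to the smaller order. An
ill-conditioned lag design (condition number above $10^{10}$) is an error
advising a shorter order or longer series.

**Normalization.** The raw $F$ scale depends on $T$ and the conditioning
set, so group statistics act on a surrogate-normalized score: the source
series is circularly shifted by uniform random offsets of at least
$m + 1$ samples (destroying cross-coupling, preserving autocorrelation),
$F$ is recomputed for each of 99 surrogates, and
$z = (F - \bar F_{\mathrm{null}})/\mathrm{sd}(F_{\mathrm{null}})$.
Testing $z$ against zero with a one-sample $t$ (BH-corrected across the
12 edges) is well-posed where testing $F > 0$ directly is not ($F$ is
nonnegative by construction). One known consequence: the null
distribution of $z$ inherits the right skew of $F$, so the edge test is
slightly anticonservative and occasional spurious edges beyond the planted
set are expected — the tests quantify this rather than hide it.

## 6. Screen and prediction

Pearson correlations (two-sided $p$ from the $t$ transform, $n - 2$ df)
between each candidate edge's $z$ and each of the six scales are
BH-corrected *within group across the edge × scale family* — the family
choice is a convention and is stated here because it affects which
correlations survive. Prediction uses a linear-kernel $\varepsilon$-SVR
($C = 1$, $\varepsilon = 0.1$; hyperparameters are conventions, not fits)
with leave-one-out cross-validation: features are standardized with
training-fold statistics only, constant features are dropped per fold and
logged, and the per-fold held-out predictions yield RMSEP and the
predicted-vs-actual Pearson correlation. There is no randomness in fold
construction or the solver, so prediction results are exactly
reproducible. Note that under label permutation the LOOCV correlation is
*negatively* biased (each held-out prediction leans on a training mean
that excludes the held-out score); "no signal" therefore does not mean
"r = 0" but "r at or below the permutation distribution".

## 7. Pipeline, seeds, and problem sizes

Every stochastic stage consumes a seed derived by hashing the master seed
with the stage name (and subject id / edge label where applicable), so
runs are bit-reproducible and insertion-order independent; the run
manifest records seeds, wall times, and artifact checksums. The stage
order is simulate → preprocess → ICA (per cohort subset; the all-subjects
decomposition feeds conditional GC and prediction) → identify → CGC →
statistics → prediction.

Problem sizes used by the shipped tests: unit fixtures run on
12 × 12 × 6 grids with short series; the end-to-end checks simulate
twenty 30-subject cohorts on a 16 × 16 × 8 grid of 3 mm voxels with the
full 250 retained volumes, SNR 2, and 99 surrogates per edge; the
planted-source dimension fixture uses 40 sources of 60 voxels support on
the default 24 × 24 × 12 grid, six subjects of 150 time points. These
sizes preserve every statistical condition of the study design (group
sizes, series length, SNR, coupling strengths) while keeping grids small
enough for routine re-runs.

## 8. Known limitations

- The surrogate-normalized edge test is mildly anticonservative (Section
  5); a rank-based normalization would fix it but would no longer be the
  stated mean/variance standardization.
- The difference-score matcher assumes templates cover a minority of the
  grid; templates covering most voxels make inside/outside means collide.
- MDL on smoothed data requires the subsampling correction and degrades
  on very small grids, where a stride at the smoothing scale leaves too
  few voxels to populate the eigenspectrum.
- The generator's nuisance sources are compact blobs; diffuse artifacts
  (global signal, scanner drift) are not modeled, and with them the
  spatial-independence premise of the ICA step would weaken.
- VAR(1) time courses have no hemodynamic lag structure; order selection
  on real BOLD data may legitimately prefer higher orders.
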