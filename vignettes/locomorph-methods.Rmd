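---
title: "Methods: landmark-based locomotor-ecology classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-based locomotor-ecology classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locomorph)
```

## The problem

Skeletal elements of extinct mammals often survive as isolated bones, yet
their shape carries a locomotor signal: in kangaroos and their relatives
(Macropodoidea), the ankle bone (astragalus) and the claw-bearing terminal
phalanx (pedal ungual) differ consistently between climbing
(arboreal/scansorial) species and terrestrial bipedal saltators. `locomorph`
implements a complete 2D geometric-morphometric pipeline that quantifies
those differences in extant species of known habit and converts them into a
probability statement about specimens of unknown habit — typically fossils.

The pipeline is: digitized outlines → fixed-count semilandmarks →
generalized Procrustes superimposition with sliding → tangent-space
covariance PCA → an iterative PC-prefix binomial logistic regression (BLR)
search with AIC selection → per-fossil prediction probabilities. A parallel
linear-measurement route (eight standard astragalar calliper measurements,
log10-transformed) runs through the same PCA/BLR machinery with the size
axis excluded. Throughout, probabilities are oriented so that values
approaching 1 mean terrestrial/bipedal-saltating and values approaching 0
mean arboreal/scansorial ecology.

## Landmark schemes

Each anatomical view has a declarative scheme (`builtin_scheme()`):

* **Astragalus** (trochlear, medial, anterior, plantar, lateral, posterior
  views): a 25-semilandmark outline curve; the medial and lateral trochlear
  crests, each as two fixed endpoint landmarks plus one apex semilandmark;
  and a 10-semilandmark navicular-facet curve — 41 landmarks, 33 of which
  slide.
* **Ungual** (dorsal, lateral views): a 20-semilandmark outline of the
  ungual process plus two fixed landmarks at the process base — 22
  landmarks, 18 sliders.

Open curves are resampled to equidistant points by arc length on the
polyline itself (linear interpolation, no smoothing spline): deterministic,
and exactly what curve digitizers mean by "equidistant". Curve endpoints are
treated as fixed because on open curves they are the only homology anchors.
The crest apex is *initialized* at the point of maximum perpendicular
distance from the endpoint chord — the operational reading of "the apex" —
and is then free to slide between its endpoints. Right-side bones are
standardized by `mirror_reflect()`, an explicit step that refuses left-side
input so a dataset can never be double-flipped silently. Slider files use
the common 3-column `before slider after` convention with 1-based indices;
the same 1-based convention is used internally (the natural choice in R —
two conventions in one code base is how off-by-one bugs are made).

## Superimposition

`gpa()` iterates: rotate every centred, unit-centroid-size configuration
onto the current mean (closed-form 2D rotation, no reflections); optionally
slide semilandmarks; re-average; renormalize the mean; stop when the mean
moves less than `tol = 1e-8` (or at `max_iter = 100`, flagged but not
fatal). Centroid size — the square root of summed squared distances to the
centroid — is stored per specimen before scaling is removed.

Sliding displaces each semilandmark only along the unit chord between its
two neighbours, minimizing either

* **bending energy** (default): the thin-plate-spline quadratic form of the
  map from the current mean to the slid configuration, solved jointly for
  all sliders; or
* **Procrustes distance**: independent orthogonal projection toward the
  mean.

Two numerical safeguards matter in practice. First, the joint
bending-energy system is near-singular along smooth tangential
reparameterizations (sliding along a near-conic arc is almost
energy-neutral), so it is solved with a tolerance pseudo-inverse
(eigenvalues below 1e-8 of the maximum are dropped); a fully singular
system falls back to the Procrustes criterion with a warning. Second, each
sliding step is scaled so no point moves more than half the distance to its
nearer neighbour — the tangent line is a local linearization of the curve,
and steps beyond the neighbour spacing leave its domain of validity
(scaling a quadratic-minimizing step never increases the criterion).

Sliding is applied during the first `slide_iter = 5` GPA iterations only,
after which plain GPA runs to convergence. This follows the behaviour of
the standard toolchains in this field, and is a deliberate deviation from
"slide every iteration": the slide/re-average alternation minimizes no
single objective, and iterating it indefinitely lets semilandmarks drift
along their tangents while the mean follows — on smooth outlines the
configuration degenerates (points pile up near fixed anchors) rather than
converging. Relatedly, the recorded `objective_trace` (summed squared
Procrustes deviation from the mean) is guaranteed non-increasing for plain
GPA and for Procrustes-distance sliding; under bending-energy sliding no
Lyapunov function exists and small increases can occur while sliding is
active.

Whether fossils take part in mean estimation is not a settled convention;
here all specimens enter the GPA (they must share one morphospace with the
extant sample), and classification is unaffected because training uses only
labelled extant specimens.

## Thin-plate splines

`tps_fit()` uses the kernel U(r) = r² log r (natural logarithm, U(0) = 0).
Conventions for sign and scaling of this kernel differ across texts; one
convention is fixed here and only relative energies are ever interpreted.
Bending energy is the quadratic form of the non-affine weights and is zero
exactly for affine maps; the same matrix (the upper-left block of the
inverse TPS system matrix of the reference) drives bending-energy sliding,
computed by one shared code path. `deformation_grid()` reconstructs the
shape at a chosen PC score (`mean + score · eigenvector`), warps a
rectangular grid bounding the mean (±10%), and accepts scores up to 1.25×
the observed range; the magnification factor `mag` (default 1) is exposed
because published figures rarely state the one they used.

## Ordination and classification

PCA is an eigendecomposition of the sample covariance matrix (n − 1
denominator) of tangent-space shape coordinates — each aligned
configuration orthogonally projected onto the tangent plane at the mean —
or of the log10 measurement matrix. Eigenvector signs are fixed so each
column's largest-magnitude loading is positive, making runs reproducible.
Covariance (not correlation) PCA is used for both data types: the landmark
setting follows the source toolchain's default, and log-covariance PCA is
the standard allometry treatment that makes measurement PC1 an
interpretable size axis — which is exactly why linear-mode classification
starts at PC2.

`fit_blr()` maximizes the Bernoulli likelihood by IRLS with an intercept.
Convergence requires the largest coefficient change to drop below `tol =
1e-8` within `max_iter = 100`. "Unreliable" fits are flagged by separation
diagnostics: any fitted probability within 1e-8 of 0 or 1, or any
standardized slope exceeding 15 in magnitude. Predictors are standardized
to unit SD internally before fitting — tangent-space PC scores have
arbitrarily small numeric scale, so a fixed cutoff on raw coefficients
would be meaningless — and reported coefficients are back-transformed.

`pc_search()` fits models on growing contiguous PC prefixes (landmark mode
PCs 1..m; linear mode PCs 2..(m+1)), stopping at the first unreliable fit —
a literal reading of iterating "until the data fail". The preferred model
is the reliable attempt with minimal AIC (= deviance + 2 × coefficients);
if no attempt is reliable the search reports `"no convergent model"` rather
than forcing one, which is the honest outcome some views of real data
produce. Prefix length is capped at `min(n_train − 2, 10)` to keep fits
away from saturation. Prefixes are contiguous rather than best-subset:
published model descriptions list ranges ("PCs 1–4"), and contiguity keeps
the search to n comparisons without multiplicity inflation. No
multiple-testing correction is applied across views; each view is an
independent analysis.

## The synthetic world

`simulate_outline_dataset()` generates a study with known truth. The base
outline is a lobed arc (low-order radial bumps on a half-ellipse — a
featureless conic would let semilandmarks slide freely, which no real bone
outline permits). Three layers of variation are added, in this order, with
a fixed RNG-draw layout so that disabling any layer does not shift the
stream:

1. **Class difference**: a fixed normal-direction displacement field,
   amplitude `0.06 sin(2πu) + 0.04 cos(πu)` in normalized arc length u,
   scaled by `class_effect_size`. Normal-directed because tangential
   differences are absorbed by sliding; fixed coefficients so the effect
   size has a stable meaning across seeds.
2. **Individual variation**: a per-specimen random smooth normal field
   (sine/cosine basis of orders 1–4, coefficient SD `individual_sd =
   0.05`). Real samples vary far beyond digitizing error, and without this
   layer the entire class signal would land on a single PC standing on bare
   digitizing noise, where any usable effect size forces complete
   separation of the training classes. The class field deliberately lies
   inside this basis's span, so the classifier faces signal embedded in
   comparable within-class variation — its intended regime.
3. **Digitizing noise and nuisance**: iid Gaussian noise (SD
   `landmark_noise_sd = 0.02` of the unit outline scale) on every traced
   point, then a random rotation (±π), translation (±50 mm) and log-normal
   scale (SD 0.2 dex around 20 mm), then resampling to the scheme counts —
   emulating the digitizer.

Fossils are drawn *at* the class-mixture mean (`fossil_mixture`: 0 = pure
arboreal/scansorial, 1 = pure terrestrial/saltating): they receive
digitizing noise and nuisance transforms but no individual deviation, so
recovery experiments measure whether the pipeline identifies the generating
morphology. The measurement generator shares this structure: an isometric
log10 size backbone (`size_sd = 0.2`, slope 1 on all eight variables),
class offsets of `0.01 × class_effect_size` on HNF/WNF (negative — smaller
navicular facet in saltators) and LLTC/LMTC/WTS (positive — elongated
crests and sulcus), and residual noise (SD 0.02).

**Calibration.** The default `class_effect_size = 2.5` was chosen once, by
scanning the recovery experiment, to give moderate morphospace overlap: the
realized Mahalanobis separation of the class means after superimposition is
about 3 SD, classes overlap in every PC, and logistic fits converge without
separation, while mean-drawn fossils are assigned with high confidence. The
100-replicate recovery benchmark runs at `n_per_class = 50` rather than the
paper-scale default of 15: the two requirements it couples — reliable
(non-separated) fits and confident fossil assignment — are antagonistic,
and at n = 15 per class the joint rate is capped near 0.75 regardless of
effect size, because the predicted log-odds of a class member have SD equal
to the class separation itself. Sample size is the only honest lever; no
threshold was adjusted.

**What a green test does and does not establish.** The generator produces
smooth, single-curve outlines with Gaussian variation, equal class sizes
and no phylogenetic structure. Green recovery tests establish that the
pipeline removes nuisance transforms, detects a known smooth class
difference, declines to report a model when the data separate, and is
calibrated at the null (fossil probabilities sit at the base rate when the
class effect is zero). They do not establish performance on real bones:
unequal and small class samples, non-Gaussian individual variation,
phylogenetic autocorrelation, digitizing-protocol drift and genuine
curve-homology ambiguity are all outside the simulated world.

## Degenerate inputs and tie-breaks

Zero-length curves, coincident landmark configurations, collinear or
duplicated TPS sources, rank-0 data matrices, single-class training labels
and out-of-range slider indices all raise immediate, specific errors. Ties
in the crest-apex rule resolve to the first maximum; straight crests fall
back to the middle point. PCA eigenvalue ties are ordered by `eigen()`'s
deterministic output; tiny negative eigenvalues from rank-deficient shape
data are clipped to zero before variance fractions are formed.

## Limitations

Strictly 2D; no missing-landmark estimation (incomplete outlines are
digitized on their preserved extent only); no phylogenetically corrected or
between-group PCA; no penalized (Firth/ridge) logistic fallback where
separation is detected — failure is reported instead, by design; and the
bending-energy/Procrustes-distance choice during sliding, which published
analyses rarely state, can shift downstream AIC values — both criteria are
exposed so the sensitivity is one flag away.
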