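---
title: "Dental surface texture and microwear analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental surface texture and microwear analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dentexture` implements a complete analysis chain for quantifying dental
wear in a controlled feeding experiment with four pelleted diets fed to
rabbits: grass meal (G, n = 7), grass meal with crushed oats (GO,
n = 6), lucerne with crushed oats (LO, n = 7) and lucerne (L, n = 6).
Dietary silica — 11.96 mg/g dry matter in the grass diet down to
0.10 mg/g in the lucerne diet — is the driving covariate: silica
phytoliths are the putative abrasive. The scientific question is how
dietary abrasiveness shapes both the *level* and the *variability* of
occlusal wear signals, measured two ways: classical 2D microwear counts
and 3D areal surface-texture parameters.

Because no raw confocal scans are available, the package ships a
first-class synthetic-surface generator that emulates the experiment;
every downstream stage (filtering, texture parameters, counting,
statistics, discriminant analysis) operates identically on real gridded
height maps read from disk.

# The surface model and its processing chain

A surface is a `height_map`: heights (µm) on a regular grid with sample
spacings `dx`, `dy`, a measured-point mask and a stage label. Confocal
instruments leave non-measured points; a field is analysed only when at
least 80% of points were recorded (`validate_measured_fraction()`,
threshold configurable). Remaining voids are filled by a deterministic
row/column-linear interpolation (`fill_nonmeasured()`), which is exact
on locally planar patches, order-independent and idempotent — adequate
below the 20% dropout ceiling, and preferable to leaving voids that
would bias convolution filters.

Three analysis stages are derived (`filter_chain()`):

* **primary** — areal Gaussian lowpass (S-filter) at a short cutoff,
  removing the smallest-scale elements and measurement noise. The
  kernel is the standard metrology Gaussian with
  $\alpha = \sqrt{\ln 2/\pi}$, which transmits exactly 50% of the
  amplitude at the cutoff wavelength; we sample it on the grid,
  truncate at one cutoff wavelength (where it has decayed below
  $10^{-6}$ of its peak) and renormalise, so constant surfaces pass
  unchanged. Borders use symmetric (mirror) padding.
* **S-F** — the primary surface minus a total-degree-2 polynomial
  fitted by least squares (F-operator), suppressing form such as the
  facet's overall curvature.
* **S-L** — Gaussian *highpass* of the S-F surface at a longer cutoff
  (L-filter), removing waviness. Highpass is computed as input minus
  lowpass, so the two components always reconstruct the input exactly.

The measurement protocol does not state cutoff values, so they are
explicit configuration with defaults chosen by the usual nesting logic:
S-filter cutoff 2.5 µm (about 8 sample spacings on the default grid —
denoising), L-filter cutoff 25 µm (a quarter of the 0.1 mm field
class), F-operator degree 2. On the S-L stage a border band of half the
L-cutoff is flagged and excluded from parameter evaluation, which
contains the Gaussian end effects without discarding the small field.

# Texture parameters

`compute_all()` evaluates 30 areal texture parameters per stage, in
five families, after cropping the flagged border band and referencing
the surface to its least-squares mean plane (mean-*plane*, not
mean-value, so residual tilt cannot bias the height moments):

* **height**: Sa, Sq, Ssk, Sku, Sp, Sv, Sz = Sp + Sv. On a constant
  surface Ssk/Sku are undefined and signalled, never silently zero.
* **spatial**: Sal and Str from the normalized areal autocorrelation
  (decay threshold s = 0.2, measured along rays in 1° steps; directions
  that never decay inside the field are capped at the field limit and
  flagged), and Std, the texture direction, from the angular power
  spectrum with parabolic peak interpolation, ties broken toward the
  smaller angle.
* **hybrid**: Sdq (RMS gradient) and Sdr (developed interfacial area
  ratio), from central-difference gradients.
* **functional**: Smr (c = 1 µm under the highest peak), Smc (p = 10%),
  Sxp (p = 50%, q = 97.5%) and the volumes Vm, Vv, Vmp, Vmc, Vvc, Vvv
  (p = 10%, q = 80%), all from the areal material-ratio
  (Abbott-Firestone) curve. The curve's inverse is implemented as the
  type-7 quantile of the height distribution; volumes are means of
  material above / void below the section height, per projected area.
* **segmentation**: watershed motifs (closed dales from surface minima,
  closed hills from maxima of the inverted surface) with Wolf pruning —
  motifs whose relief is below 5% of Sz are merged (the ISO-style
  default; the protocol is silent, so it is configuration-exposed). The
  watershed is delegated to `EBImage::watershed()`, whose tolerance
  argument implements exactly this relief-based merging. Each motif
  reports its area, its volume relative to its bounding saddle (pour
  point of the rim) and its extreme height. From these: Spd, Spc (local
  5×5 quadric fits at hill peaks — finite-difference curvature is too
  noise-fragile), S5p, S5v, S10z = S5p + S5v, and the arithmetic means
  Sda, Sha, Sdv, Shv. Arithmetic means over closed motifs follow ISO
  convention; the protocol does not say mean vs total.

Two readings were genuinely open and are pinned here: Smr's section
height is referenced to the highest peak (the literal reading of
"c = 1 µm under the highest peak"), and pit/hill extremes are measured
from the mean plane.

# The synthetic generator: what it emulates

`generate_surface()` builds each raw surface as

> form (quadratic bowl, ~4 µm sag) + waviness (two low-frequency
> sinusoids, 50 and 80 µm, random phases) + rendered wear features +
> white residual roughness + random non-measured dropout (5%).

Wear features are smooth elliptical-Gaussian depressions
(`render_feature()`; semi-axes length/2 and width/2, truncated at three
semi-axis lengths so disjoint features commute). Feature counts are
Poisson with per-animal rates; each animal's rate, depth and roughness
multipliers are log-normal with mean 1 and the group's between-animal
coefficient of variation. Scratch orientations follow a von Mises
distribution (axial, period 180°) around a fixed chewing direction.

The four diet groups differ only through their `diet_group_config`,
and everything is coupled to log(silica):

| quantity | grass end (11.96 mg/g) | lucerne end (0.10 mg/g) | anchored by |
|---|---|---|---|
| pit rate / counting square | 21.7 | 45.9 | published group means of Np |
| mean scratch length | 59.1 µm | 38.9 µm | published group means of Ls |
| scratch rate | 36 | 18 | chosen: scratch-dominated vs pit-dominated |
| orientation kappa | 8 | 1.2 | chosen: aligned vs near-isotropic scratches |
| between-animal CV | 0.12 | 0.45 | chosen to reproduce the variability ordering |
| micro-pit rate | 10 | 80 | chosen: fine pitting on low-abrasion enamel |
| residual roughness | 0.04 µm | 0.36 µm | chosen: slow, uneven overwriting |

The intermediate diets take silica values 3.2 (GO) and 3.0 (LO) mg/g —
not printed for the original feeds; they are set close together because
the two oat-containing diets behaved almost identically in the
experiment — and all couplings interpolate affinely in log(silica).

Two generator populations deserve comment, because they are the
mechanism behind the texture-level findings rather than direct
calibration targets. *Micro-pits* (median 3 µm) appear only on the 3D
surfaces, not in the 2D counting fields: they are below what the
stereomicroscope protocol resolves, but on the confocal scale they
fragment the watershed partition of low-abrasion surfaces into many
small dales, reproducing the lower mean closed-dale area (Sda) of the
lucerne group against the large lesion areas of the grass group. The
*residual roughness* term is larger and relatively more variable on
low-abrasion surfaces: wear traces there accumulate slowly and
unevenly instead of being constantly overwritten, which yields the
higher and more variable maximum peak height (Sp) on the S-L surface
in the lucerne group. Both couplings are fixed defaults of the
generator, chosen once as the package's model of low- versus
high-abrasion enamel.

The 2D microwear protocol observes a 300×300 µm counting square at
lower magnification than the 160×160 µm confocal field, so the counting
field is simulated as a separate, coarser realisation of the same
feature process (a 360 µm field with a 30 µm margin; features counted
when their centre falls in the square, inclusive lower/left, exclusive
upper/right). Pit "diameter" is the feature's major axis; the
pit/scratch boundary is a length:width aspect ratio of 4 — the manual
protocol counts by eye, so a reproducible rule had to be pinned.

What the generator does *not* emulate: enamel microstructure and chip
formation, cumulative wear over time, prism-level anisotropy of real
enamel, instrument-specific artefacts (speckle, batwings), or any
physical relation between silica hardness and scar geometry. Passing
tests therefore show that the *pipeline* recovers the planted
structure, not that real rabbit surfaces would behave this way.

# Robust statistics

Each variable is compared across groups exactly as the experimental
protocol prescribes:

* **Welch-Yuen omnibus** (`wy_omnibus()`): Welch's heteroscedastic
  F on 15%-trimmed means, with weights from winsorized variances
  (per group $d_j = (n_j-1)s^2_{wj} / (h_j(h_j-1))$, $h_j = n_j - 2g_j$,
  $g_j = \lfloor 0.15\, n_j \rfloor$); nu1 = k−1 and a
  Satterthwaite-type nu2. For two untrimmed groups it reduces exactly
  to the squared Welch t.
* **Pairwise comparisons** (`pairwise_t3()`): Yuen-style trimmed-mean
  statistics with Welch degrees of freedom per pair, familywise-
  controlled with studentized-maximum-modulus critical values (the
  T3 idea). There is no closed form; critical values come from
  Monte-Carlo with a fixed internal seed (draws cached per degrees of
  freedom), with a closed-form Šidák fallback selectable and flagged.
* **Cliff's method** (`cliffs_method()`): the dominance statistic
  $\delta = P(x>y) - P(x<y)$ by exact enumeration, Cliff's unbiased
  variance estimator from the dominance matrix, the standard
  asymmetric confidence interval, and a two-sided normal-reference p.
  Under complete separation the variance estimate is zero; the p value
  is then the minimal achievable two-sided level
  $2/\binom{n_x+n_y}{n_x}$ and the result is flagged. Cliff p values
  are *not* familywise-adjusted across the six pairs (the protocol
  does not say they were), which is noted in the output.
* **Dual significance**: a contrast is reported only when both the
  pairwise trimmed-mean test and Cliff's method give p ≤ 0.05
  (non-strict), an intersection rule whose size is never larger than
  either test's alone.
* **Variability profiles**: medians, type-7 quartiles, IQR and
  1.5-IQR whiskers — the quantile rule is pinned so IQR orderings are
  reproducible.

# Discriminant analysis

`stepwise_select()` implements forward stepping on the partial Wilks-
lambda F statistic with F-to-enter = 1 and F-to-remove = 0.9 (the
removal threshold below the entry threshold guarantees termination);
the statistic's exact form is pinned here because the original software
names only the thresholds. `canonical_da()` solves the between/within
generalized eigenproblem, orders axes by eigenvalue, centres scores on
the grand mean, scales coefficients to unit pooled within-group score
variance, and fixes the sign of each axis by making its largest-
magnitude coefficient positive — axis signs are otherwise arbitrary and
would break reproducibility. When stepping selects fewer than two
variables, the two strongest candidates by single-variable partial F
are used so a two-dimensional factor space always exists.

Two kinds of 90% regions are drawn in the canonical plane.
`centroid_ellipses()` gives *confidence regions for the group
centroid* — the group score covariance scaled by $\chi^2_{0.90,2}/n_g$
— matching the protocol's "group centroids … with confidence intervals
of 90%". `factor_space_ellipses()` gives the group's *factor space*,
the data-concentration region (covariance scaled by $\chi^2_{0.90,2}$,
no $1/n$): its size reflects the within-group variability itself.
Statements about groups occupying distinct or overlapping factor
spaces are judged on the factor-space regions, because centroid
regions shrink with sample size and would separate even two groups
with identical score distributions; the reported pipeline carries
both. Ellipse disjointness/overlap is decided by boundary sampling at
1° resolution.

# Numerical choices and degenerate inputs

* Filter kernels are normalized to unit sum; DC transmission is exact.
* Form removal uses a monomial basis on [−1, 1]-scaled coordinates for
  conditioning; residuals have exactly zero mean.
* The autocorrelation is the linear (zero-padded) estimate normalized
  per-lag, interpolated bilinearly along rays; crossing radii are
  linearly interpolated between steps.
* Watershed labels are computed on relief shifted to be strictly
  positive; motif volumes are measured against the pour point (rim
  extreme) of each motif.
* Constant surfaces: Ssk/Sku signalled undefined; segmentation refuses
  (no motifs); the material-ratio curve degenerates gracefully
  (Smr = 100%, zero volumes).
* Ls is undefined (`NA`, flagged) when no scratch lies in the counting
  square; such animals drop out of Ls group statistics only.
* All randomness is seeded: per-animal seeds derive from a master seed
  by a deterministic hash, internal Monte-Carlo references use fixed
  documented seeds and restore the caller's RNG state.

# Problem sizes

The default synthetic grid is 512×512 points over 160×160 µm
(dx ≈ 0.31 µm), matching the scale of the 3D surface models of the
original study. The package's own test and acceptance runs use
256×256 grids (dx ≈ 0.63 µm) and the height + segmentation parameter
families for replicate experiments — the headline variables (Np, Ls,
Sda on primary, Sp on S-L) are stable at this resolution, as spot
checks against the 512-point default confirm — and 10 replicate
experiments for pattern-recovery rates, 20 for generator calibration,
10,000 null simulations for test size and 5,000 for ellipse coverage.

# Known limitations

* The generator's silica couplings beyond the two published anchors
  (Np, Ls group means) are the package's own model; within-group
  dispersions of the original data were never published, so the
  between-animal CVs reproduce orderings, not magnitudes.
* Sal/Str depend on the linear-ACF estimator and the 1° ray
  resolution; strongly anisotropic fields report a capped Str.
* The x3p-style container is a minimal plain-XML interchange record,
  not a standards-conformant x3p file.
* No multiple-testing correction is applied across the ~100
  variable×stage combinations, mirroring the original analysis; the
  dual-significance rule is the only guard.
* Scale-sensitive fractal analysis is out of scope.
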