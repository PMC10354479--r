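---
title: "Methods: ontogenetic allometry, wing planforms and flight performance"
author: "pterowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontogenetic allometry, wing planforms and flight performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pterowing)
```

Pterosaurs hatched at wingspans of a few tens of centimetres whatever their
adult size, so giant forms must have grown through an enormous size range.
This package reconstructs how wing shape and flight performance changed
along that growth trajectory, for five taxa spanning the small-bodied
(anurognathids, *Rhamphorhynchus*, *Pterodactylus*, *Sinopterus*) to the
giant (*Pteranodon*).  The pipeline runs from specimen measurement tables
through multivariate allometry, power-law extrapolation, geometric planform
reconstruction, and an actuator-disc flight model, to pair-wise permutation
comparisons.  This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic data generator does and does
not emulate.

## Specimen tables and wingspan

The unit of data is a table of per-specimen skeletal measurements in
millimetres over a fixed 13-dimension vocabulary (skull, neck, tail,
humerus, ulna/radius, metacarpal IV, wing phalanges WP1--WP4, femur, tibia,
wingspan); fossil incompleteness is represented by absent cells.  Wingspan
is defined skeletally as 2.1 times the summed forelimb elements
(`compute_wingspan()`), so it is computable only for specimens with a
complete forelimb.  Millimetres are used internally throughout; wingspans
cross to metres at exactly one point (the growth-series grid), so unit
errors cannot accumulate.  Empty CSV cells and `NA` both mean "absent";
zero is never a valid length.  Where a source records a single forelimb
value for ulna or radius, the reader stores it in the combined
`ulna_radius` column and makes no attempt to decide which bone it was.

## Multivariate allometry

For one taxon the specimens are treated as points on a shared growth
trajectory.  On natural-log scale the model is
`log Y_ij = a_j + b_j s_i + e_ij`, with `s_i` a latent size and `b_j` the
growth-allometric coefficient of dimension `j`.  `allometry()` estimates
`b` as the first eigenvector `u` of the covariance matrix of the completed
log measurements, rescaled by Jolicoeur's convention `AC_j = u_j sqrt(p)`
(`p` dimensions), so isometry means every `AC = 1`.  The alternative
normalisation `p u_j / sum(u)` is available behind the `normalization`
flag; both reduce to 1 under isometry.  The covariance (never the
correlation) matrix is used: allometric coefficients are log--log slopes
and correlation would erase the scale information.

A normalisation subtlety matters when comparing against published
coefficient tables: `sum(AC^2) = p` holds over the dimensions *actually
analysed*.  A published table that prints only the limb and wingspan
coefficients closes this constraint only once the axial dimensions (skull,
neck, tail) are included.  The preset coefficient vectors in this package
therefore carry axial entries that complete the constraint exactly (with
positive skull and neck allometry for *Rhamphorhynchus* and
*Pterodactylus*, as reported for those taxa); the *Pteranodon* sample is
postcranial-only and its ten printed values already sum to `p` within
rounding.

**Missing data.**  Fossil tables are mostly incomplete (59 *Pteranodon*
specimens, most fragmentary), and complete-case PCA would discard nearly
everything.  Missing cells are completed by rank-1 EM
(`impute_log_missing()`): initialise at column means, then alternate
column-recentring, leading singular component, and reconstruction of the
missing cells, until the largest update falls below `tol = 1e-8` or 500
iterations.  On noise-free rank-1 data this converges to the unique rank-1
completion; non-convergence is reported in the result rather than raised.

**Uncertainty and classification.**  One-tailed 95% bounds come from a
nonparametric bootstrap over specimens: `B = 1000` resamples (seed recorded
in the object), AC re-estimated per replicate, percentile method with
type-7 interpolation.  A dimension with point `AC < 1` gets the 95th
percentile as an upper bound, otherwise the 5th percentile as a lower
bound, and is classified `-` if an upper bound lies below 1, `+` if a
lower bound lies above 1, and `=` otherwise.  Imputation is run once on
the full table and the bootstrap resamples rows of the *completed* matrix;
re-imputing inside every replicate would multiply cost several-hundred-fold
while adding little variance at the ~10% missingness typical here.
Replicates in which any dimension degenerates to zero variance are
discarded; more than 10% discards is an error.

## Growth extrapolation

Given coefficients and a measured seed specimen, any dimension is carried
to another wingspan by `Y2 = Y1 (Z2/Z1)^(b_y/b_z)`, evaluated in log space
(`extrapolate_dimension()`).  The default grid is 0.3 m to 7 m in 0.1 m
steps (the seed wingspan is inserted exactly), chosen as a fine grid over
the juvenile-to-giant range; evaluation is cheap, and trends on this grid
are what the comparisons consume.  The three trunk offsets -- L1 (humeral
head to midline), L2 (femoral head to midline), L3 (shoulder-to-hip
distance along the midline) -- grow isometrically (`b = b_z`): there are
no ontogenetic data for soft-tissue trunk outlines.  Seed trunk offsets
default to 3.5%, 2.5% and 12% of the seed wingspan, approximations from
typical published skeletal reconstructions, and are user-settable per
taxon.

## Planform geometry

The single wing is assembled in a frame with x lateral, y anterior and the
midline at x = 0.  The shoulder sits at `(L1, 0)`; the forelimb elements
chain outward at per-segment sweep angles (a `posture`); the femur leaves
the hip `(L2, -L3)` at 45 degrees postero-laterally and the tibia runs
parallel to the midline.  The membrane trailing edge is a cubic Bezier
from the ankle (P0) to the wingtip (P3 = P2), with P1 at the intersection
of two construction lines at 30 degrees to the tibia and to the distalmost
wing phalanx.  The lines are anchored at the curve endpoints (the only
defensible anchors, since no other anchor is specified by the
construction), and of the two 30-degree families through each anchor the
pair that encloses the membrane is used: the ankle line climbs
antero-laterally, the tip line runs just posterior of the leading edge.
This pairing is not arbitrary: it is the only one of the four that yields
both a valid control point between root and tip and planform aspect ratios
in the range published for these taxa (about 8--17); the alternatives
produce aspect ratios near 3 or an anterior control point.

The outline closes along the midline (midline point, shoulder, leading
edge, wingtip, trailing-edge samples, ankle, hip, midline), so the
single-wing area *includes* the half-trunk strip and *excludes* the
uropatagium (its published reconstruction is not specified quantitatively
enough to reproduce; excluding it affects absolute areas slightly, trends
not at all).  Area is the shoelace formula on `n = 1024` Bezier samples;
against an exact Green's-theorem evaluation of the Bezier-bounded region
the discretisation error is below 0.05%.  Wing area is twice the
single-wing area; aspect ratio is `Z^2 /` wing area in SI units.  Outline
simplicity is verified on a reduced polygon that keeps every joint vertex
and subsamples only the trailing-edge arc (decimating joints can
manufacture false crossings).

**Postures are configuration, not ground truth.**  The taxon presets
approximate published wing reconstructions: one pterodactyloid posture
shared by *Pteranodon*, *Sinopterus* and *Pterodactylus* (anteriorly swept
proximal wing, which balances centre of mass against centre of pressure),
separate rhamphorhynchid and anurognathid presets, and a neutral posture
with the leading edge essentially perpendicular to the body axis.  All
angles ship as editable values (YAML round-trip provided).  Absolute
aspect-ratio endpoints therefore depend on posture digitisation and are
approximate; trend *directions* are robust to the posture choice, and the
test suite asserts exactly that.

## Mass, wing loading and the flight model

Body mass comes from either of two published wingspan scaling equations
per group: `0.681 Z^2.807` (non-pterodactyloids) and `0.519 Z^2.550`
(pterodactyloids), or `0.3 Z^2.74` and `0.315 Z^2.56`.  Wing loading is
`M /` wing area.

Flight performance uses a self-contained actuator-disc formulation with
every constant exposed in `aero_config()`:

* induced power `P_ind = k (M g)^2 / (2 rho V S_d)`, disc area
  `S_d = pi Z^2 / 4`, induced-power factor `k = 1.2`;
* parasite power `P_par = 0.5 rho V^3 S_b C_Db`, body frontal area
  `S_b = 0.00813 M^0.666` m^2, body drag coefficient `C_Db = 0.1`;
* profile power `P_pro = (X1 / AR) P_am` with `X1 = 8.4`, held independent
  of speed, where `P_am` is the absolute minimum of `P_ind + P_par`;
* air density fixed at 1.225 kg m^-3 (no altitude model), `g = 9.81`.

Holding profile power speed-independent is the classic simplification that
gives the minimum power speed a closed form `Vmp = (A/3B)^(1/4)` with
`A = k (M g)^2 / (2 rho S_d)` and `B = 0.5 rho S_b C_Db`; the package
nevertheless finds `Vmp` by bounded minimisation on [0.1, 200] m s^-1
(tolerance 1e-6), so the profile rule can be changed without invalidating
the optimiser, and the closed form serves as an independent oracle in the
tests.  A minimiser at either search bound signals an unphysical
configuration and errors.  Because this formulation is not the external
flight-modelling package used to produce the published performance curves,
absolute outputs are not expected to match it; the package's claims about
flight performance are structural (U-shaped curve, energy-balance
identities, monotone ontogenetic trends) and are asserted as such.

Derived indices at `Vmp`: total drag `D = P(Vmp)/Vmp`; basal metabolic
power `P_BMR = 3.277 M^0.624` W; flight efficiency
`COT^-1 = Vmp M / P_BMR` (basal power in the denominator, exactly as the
index is defined); sinking rate `Vz = D Vmp / (M g)`; glide ratio
`Vmp / Vz = M g / D`.  The forward speed entering the glide ratio is taken
as `Vmp` (no separate best-glide speed is estimated); users can probe the
sensitivity by evaluating `power_curve()` at other speeds.

## Pair-wise comparison

Performance series of two taxa are compared at identical wingspan grid
points (no interpolation) by a paired sign-flip permutation test
(`paired_permutation_test()`): statistic = mean paired difference, null
generated by independent sign flips, two-sided.  With up to 20 pairs all
`2^n` patterns are enumerated exactly (the observed arrangement counts, so
`p > 0`); beyond that, Monte-Carlo with `1e5` draws and add-one
correction.  The exact route replaces the asymptotic approximation of the
usual implementations because the grids here give only a few dozen pairs
and exactness is cheap and reproducible.  The statistic (mean rather than
sum or a studentised variant) is the simplest member of the symmetry-test
family; since sign-flip enumeration is invariant to positive rescaling,
the choice does not affect the p-value's validity, only its power profile.
Tests are emitted for all four posture-by-mass-model combinations, and no
multiple-testing correction is applied (none is applied in the analysis
this mirrors).

## The synthetic specimen generator

`generate_taxon()` draws tables from the same log-linear model the
estimator assumes: latent sizes log-uniform between bounds (log-uniform so
small specimens are as frequent as large ones; real fossil samples are
size-biased, which is *not* emulated), `log Y = a + b s + e` with
`e ~ N(0, sigma^2)`, and missing-completely-at-random deletion.  Wingspan
is generated as a measured column with its own coefficient, matching its
role in the PCA; the 2.1-formula applies to `compute_wingspan()` only.
Intercepts derive from per-taxon reference element proportions (synthetic
configuration, chosen to give plausible adult shapes) scaled so the
formula wingspan at the reference size equals the nominal wingspan.

Two specimens are generated noise-free exactly at the size bounds
("anchors", exempt from deletion), and other specimens' noise is redrawn
until their formula wingspan falls inside the configured range; generated
complete-specimen wingspans therefore span, and stay within, the
configured range by construction.  The anurognathid reference proportions
(short distal phalanges, long hindlimbs) were set so the reconstructed
planform matches the published anurognathid aspect-ratio level (~9);
without that the synthetic anurognathid wing was implausibly narrow.

`preset_library()` provides one configuration per study taxon: published
coefficient vectors (axially norm-completed as above), published wingspan
coverage (0.30--1.28, 0.19--0.74, 0.81--2.17 m; 1.76--6.37 m for
*Pteranodon*, whose analysed sample includes small incomplete specimens;
0.20--0.50 m assumed for anurognathids, for which no range is published)
and published sample sizes (88, 22, 10, 59; 16 assumed for
anurognathids).  Noise `sigma = 0.05` on the log scale: a
back-calculation from the published one-sided confidence-interval widths
(`gap / 1.645 x sd(log size) x sqrt(n)`) gives 0.03--0.06 across taxa, so
0.05 is a realistic single default.  MCAR rate 0.1.  The anurognathid
preset generates WP3 and WP4 at the shared combined coefficient and flags
the combined `wp34` convention for analysis (the presence of WP4 in
juvenile anurognathids is uncertain, so the two phalanges are analysed as
one dimension).

**What passing tests show, and what they do not.**  The generator shares
the estimator's model family, so parameter-recovery results demonstrate
correctness of the implementation, identifiability at realistic n/noise,
and calibration of the bootstrap -- not robustness to taphonomic
size-dependent missingness, measurement covariance between elements, or
trajectory curvature, none of which are modelled.  Reproduction of
published point coefficients from the synthetic reconstruction is a
consistency check of the whole pipeline, not a reanalysis of the original
specimen data: the published `+/-/=` classifications encode the original
sample's confidence-interval widths, which no synthetic sample reproduces
cell-for-cell.  In repeated simulation at the preset conditions about 85%
of dimension-by-taxon classifications match the published table; the
mismatches concentrate where a printed class contradicts the sign of its
own printed coefficient (possible only under the original data's CI
widths).

## Numerical choices and degenerate inputs

* Imputation: tolerance 1e-8 (log scale), max 500 iterations; empty rows
  or columns are errors; fewer than 3 usable specimens is an error.
* Zero-variance dimensions are rejected by name before eigenanalysis.
* Eigenvector sign is fixed by requiring a positive mean loading.
* Quantiles: type-7 (R default) percentile bootstrap.
* Bezier discretisation: 1024 samples for areas; SVG export writes the
  native cubic path.
* Degenerate trailing-edge constructions (parallel lines, control point
  outside the root--tip span) raise errors carrying the offending
  coordinates.
* `optimize()` tolerance 1e-6 m s^-1 for `Vmp`; minimiser within 1e-3 of a
  bound errors.
* Exact permutation enumeration is chunked at 2^16 patterns to bound
  memory; ties against the observed statistic count as extreme within
  1e-12 relative tolerance.
* Seeds: every stochastic routine takes and records an explicit integer
  seed; identical configuration implies byte-identical output.

## Problem sizes used by the test suite

The suite favours sizes that make sampling error negligible relative to
the asserted tolerances while keeping a full run in a few minutes: 200
replicates for bootstrap-coverage simulation, 100 seeded fits for
parameter recovery at n = 60, 20 seeds x 5 taxa for preset recovery, 2000
simulated nulls for the permutation level, 40 random cases against the
exact-enumeration oracle, and 1024/2048-point discretisation comparisons
for areas.  These were chosen as comfortable sizes for the statistical
checks involved, and the binomial/Monte-Carlo tolerances in the tests are
matched to them.

## Known limitations

* No propatagium, no uropatagium, no 3-D camber, no membrane attachment
  variants other than the ankle; planforms are projections.
* Point extrapolation only: coefficient uncertainty is not propagated into
  growth series, planforms or performance (as in the analysis this
  mirrors).
* The flight model omits flapping kinematics, anaerobic power limits,
  soaring environments, and agility/manoeuvrability indices.
* The latent-size model is a single log-linear axis; ontogenetic shifts in
  allometry (heterochrony) are not representable.
* Taxon postures and trunk offsets are editable approximations; absolute
  wing areas and aspect-ratio endpoints inherit that uncertainty.
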