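---
title: "Physical-disector stereology and synapse morphometry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical-disector stereology and synapse morphometry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synstereo)
```

# The problem

Counting synapses in serial-section electron microscopy (ssSEM) is an
estimation problem with two systematic hazards. First, profile counting in
single sections is biased by object size and orientation; the *physical
disector* removes this bias by counting only objects whose profile is present
in a reference section but absent in a parallel look-up section, inside an
unbiased counting frame. Second, the tissue that is imaged is not the tissue
that was alive: EM staining, resin embedding and ultramicrotomy deform the
sample, so raw densities per ultrathin-section volume misstate the wet-tissue
(near in-vivo) density unless the deformation cascade is calibrated.

`synstereo` implements both parts, together with the morphometric toolkit
that accompanies them (log-normal size statistics, minimum-bounding-sphere
Feret diameters, a geometric model of synapses missed between cutting
planes), group-level inference (jackknife, bootstrap, random-intercept mixed
models), and a synthetic-tissue generator so that the entire chain can be
validated against known ground truth. The motivating application is the
songbird premotor nucleus HVC, where asymmetric (excitatory) and symmetric
(inhibitory) synapse densities are compared across treatment groups of
developing birds, but nothing in the package is specific to that system.

# The deformation cascade

Four dimensionless factors map measurements from the ultrathin-section state
back to the wet state:

* **Embedding, `Re`.** Staining and embedding are taken as isotropic. From
  landmark distances $S$ measured in the same section before and after
  embedding, $R_e = \left(\overline{S_\text{emb}/S_\text{wet}}\right)^3$.
  Typical magnitude: a 2.2% linear dilation per axis, i.e. $R_e \approx 1.067$.
* **Cutting, `RX`, `RY`.** Ultramicrotomy is anisotropic: the axis
  perpendicular to the cutting direction barely changes (about +1.4%), the
  cutting axis shrinks strongly (about -17.9%). Both are mean landmark-distance
  ratios between ultrathin and embedded sections.
* **Thickness, `t_bar`, `RZ`.** Section thickness is estimated by the
  cylindrical-diameters method: a longitudinally cut mitochondrion of
  diameter $d_i$ spanning $s_i$ sections gives $\bar t = \frac1N\sum d_i/s_i$
  and $R_Z = \bar t / 70\,\mathrm{nm}$. We count $s_i$ as the number of
  section *boundaries* between the first and last appearance (an object seen
  in sections $k_1..k_2$ has $s = k_2-k_1$). This convention makes
  $\mathbb{E}[d/s] \approx t$ with bias of order $(t/d)^2$; counting the
  number of *slabs* instead ($k_2-k_1+1$) would underestimate thickness by
  roughly $t/(d+t)$, over 10% for realistic mitochondria.
* **Cumulative, `Rcum`** $= R_e R_X R_Y R_Z$, the total volume change.
  Densities calibrate as $\rho_\text{wet} = \rho_\text{ultrathin} \cdot
  R_\text{cum}$ (counts are conserved; volumes divide).

Mean-of-ratios, not ratio-of-means, is used throughout, matching the
per-landmark definition of the factors. Per-sample `Rcum` values are composed
from per-sample factors; the package never averages factors across samples
before multiplying.

A deliberate modelling point: when the measured thickness $\bar t$ is used
both in the disector volume (raw density $\propto 1/\bar t$) and in
$R_Z \propto \bar t$, its measurement error cancels exactly in the calibrated
product. `simulate_disector_experiment()` follows that convention.

# Disector counting

A disector pairs a reference with a look-up section `lookup_offset = 2`
sections away (140 nm at 70-nm sections) and one intermediate section in
between; the intermediate section is continuity evidence only and never
changes the count. The disector height is the reference-to-look-up
separation, 140 nm by default. A 5 x 5 um counting frame admits a profile
that overlaps the frame or touches the right/top (inclusion) edges and
rejects any profile touching the left/bottom (exclusion) edges or their
shared corner; tangency to an inclusion edge counts, tangency to an exclusion
edge never does. With frames tiling the plane this counts every profile
exactly once, which the test suite verifies directly by translating a tiling
over random tissue. Which physical edges carry which role is a convention;
the standard left+bottom exclusion is used.

Counting is unidirectional (reference to look-up) by default, with
bidirectional counting available as an option.

The density estimate is
$\hat\rho = \sum Q^- \big/ \sum (A \cdot h)$
over all disectors ($A$ frame area, $h$ disector height), then calibrated by
`Rcum`. Disector theory says estimates stay within a few percent of truth
when consecutive disectors are separated by no more than twice the mean
object size and at least on the order of a hundred disectors are inspected;
the default `ref_step = 6` sections (420 nm) keeps the separation at about
twice the ~200-nm mean synapse diameter, and the simulation suite checks a
&lt;6% mean absolute error under exactly those conditions.

# The synthetic tissue model

`generate_tissue()` places each synapse type as an independent homogeneous
Poisson process (so density estimators are tested against a true rate, not a
conditioned count). Per object:

* physical volume $V$: log-normal per type;
* cleft thickness $c$: uniform on a per-type interval, 20-40 nm for
  symmetric synapses and 30-50 nm for asymmetric ones (asymmetric clefts are
  wider; the exact interval is a generator default, not an asserted
  biological value);
* geometry: an oriented disk with diameter equal to the Feret diameter,
  thickness equal to the cleft, $D = \sqrt{4V/(\pi c)}$, and orientation
  uniform on the sphere. The disk proxy is chosen because the miss model
  (below) is about flat objects slipping between planes; a disk captures
  exactly that geometry.

Defaults emulate the reported study conditions: total density
$7\times10^8/\mathrm{mm^3}$ (inside the printed $5$-$8\times10^8$ range), a
20% symmetric fraction (the isolate-group value), mean Feret diameters of
200 nm. When `size_log_mu` is not given it is derived from `feret_scale` via
$\mathbb{E}[D] = \tfrac{2}{\sqrt\pi}\,\mathbb{E}[c^{-1/2}]\,e^{\mu/2+\sigma^2/8}$,
with $\sigma = 0.8$ on log-volume (a typical synapse-size spread; the source
study prints no per-type distribution parameters, so this is a package
default stated here, not a reproduced value).

Mitochondria are cylinders with in-plane axes (the configuration the
thickness method requires), 20 per block, diameters 300-800 nm.

What the generator does **not** emulate: EM texture, vesicles and membranes,
segmentation errors, spatial clustering of synapses, correlated orientations.
Passing tests therefore validate the estimators' statistical behaviour under
the stated geometric model, not the segmentation pipeline upstream of them.

## Sectioning conventions

`section_tissue()` supports two footprint conventions, because two different
questions are asked of it:

* `"slab"` (default): a footprint in every 70-nm slab the object's z-extent
  intersects. This is the physical ssSEM picture -- the whole slab is
  projected into the image -- and is what disector counting consumes.
* `"plane"`: a footprint only where a cutting plane is crossed. A flat,
  thin object lying between two consecutive planes leaves no footprint.
  This is the geometry of the missed-synapse model.

# The missed-synapse model

An oriented disk with diameter $D$, thickness $c$ and normal at angle
$\varphi$ from the cutting axis has z-extent $e = D\sin\varphi +
c\cos\varphi$; under uniform orientations $u = \cos\varphi \sim U(0,1)$.
`miss_probability(D, c, h)` returns $P(e < h)$, in closed form from the
quadratic $(D^2+c^2)u^2 - 2hcu + (h^2 - D^2) > 0$ with roots
$u = \big(hc \pm D\sqrt{D^2+c^2-h^2}\big)/(D^2+c^2)$. For the printed
geometry $D = 200$, $c = 20$, $h = 70$ nm this is 0.0326.

Two readings of this number must be kept apart. $P(e<h)$ is the **at-risk**
probability: the object *can* fit between consecutive planes. Whether it is
actually missed also depends on where it sits; under a uniform z-position
the truly-missed fraction is $\mathbb{E}[(h-e)_+]/h$, strictly smaller
(about 0.009 for the same geometry). The closed form is the right quantity
for an "at most" bound -- which is how the field uses it -- and the test
suite checks both: the at-risk fraction computed from `section_tissue()`
z-extents matches the closed form, and the empirical zero-footprint fraction
under the `"plane"` convention is positive but bounded above by it.

A flat-lying synapse has $e = c$, so only clefts below about $h/3 \approx
23.3$ nm (at $h = 70$) put a synapse at material risk once typical tilt is
accounted for; `classify_threshold()` returns that cut-off. Averaged over the
printed geometry ($D \approx 200$ nm, $c \sim U(20, 40)$ nm), the population
at-risk probability lands near 2%, inside the 0.5-3.5% bracket the tests
assert -- consistent with the order of magnitude reported for missed
symmetric synapses.

# Size statistics and the Feret diameter

Sizes are summarised on the log scale: $W_i = \log V_i$, $\mu$ and $\sigma^2$
the sample mean and variance, $\bar V = e^\mu$ (the geometric mean /
log-normal median -- deliberately not the linear mean), and
$SE = \sqrt{\mathrm{var}/N}$ with $\mathrm{var} = e^{2\mu+\sigma^2}
(e^{\sigma^2}-1)$, the linear-scale log-normal variance. At small-to-moderate
$\sigma$ this SE tracks the bootstrap standard error of $e^{\hat\mu}$ (the
suite checks 15% agreement at $N=300$, $\sigma=0.25$); at large $\sigma$ it
is conservative relative to the sampling error of $e^{\hat\mu}$, which is
worth knowing when comparing error bars across analyses.

Goodness of fit of $W_i$ to a normal is reported two ways: the plain
Kolmogorov-Smirnov p-value against the *fitted* normal (whose null is
optimistic because $\mu,\sigma$ were estimated from the same data) and the
Lilliefors-corrected p-value. The package reports both and interprets
neither; users comparing against literature values should note that some
published KS usages read small p as *supporting* the fitted distribution,
which is the opposite of the test's construction.

**Feret diameter** here follows the synapse-morphometry usage: the diameter
of the *minimum bounding sphere*, computed exactly by Welzl's expected
linear-time randomized algorithm (move-to-front, support sets of at most 4
points). This is not the conventional maximum-caliper Feret diameter; for
convex bodies the two coincide only in special cases. The implementation is
verified against full support-subset enumeration on small point sets and
against the KKT optimality certificate of the minimum enclosing ball (all
points enclosed, centre in the convex hull of the boundary support) on sets
up to 50 points.

# Group statistics

**Jackknife.** The percent-symmetric ratio estimator $q = 100\sum N^s_i /
\sum N_i$ gets its variance from leave-one-disector-out resampling,
$\sigma_q^2 = \frac{n-1}{n}\sum_i (q_i - \bar q)^2$. The leave-one-out mean
$\bar q$ equals $q$ only for homogeneous disectors; for a ratio estimator
they differ in general, so both are reported rather than forced equal.

**Bootstrap.** Group comparisons simulate experiments with per-animal
Gaussian draws at the observed per-animal means and SDs; the p-value is the
fraction of simulated experiments in which the effect direction reverses.
Both one-sided fractions are computed from the *same* draws, so swapping the
groups maps $p \mapsto 1-p$ exactly.

**Mixed models.** Densities (or per-partition percent-symmetric estimates)
are modelled as $y_{im} = \beta_\text{base} + \beta_\text{group} + b_m +
\varepsilon_{im}$ with a random intercept per animal, fitted by maximum
likelihood via `lme4`, with Wald p-values for $\beta \ne 0$ and `df` reported
as observations minus fixed effects. A mandatory test compares the fit
against an independently coded profile-likelihood optimizer. For the
percent-symmetric variant, each animal's disectors are split into four
interleaved partitions and the model is fitted to the per-partition
estimates (four observations per animal); the interleaving is deterministic,
so results are reproducible without an extra seed. Both disector-level and
partition-level layouts are available, since published degrees of freedom
suggest tools differ in which layout they use.

**Regional volume.** $V_{sec} = n\,p\,d$ per section, summed over sections,
averaged over hemispheres -- plain arithmetic, included so that the full
analysis chain lives behind one interface.

# Numerical and design choices

* **Coordinates**: right-handed, z is the cutting axis; sections are indexed
  from 0; voxel boxes are half-open. Lengths are um for coordinates, nm for
  object sizes and thicknesses; densities are per mm^3 in all public output.
* **Frame-rule ties**: closed comparisons; tangency to inclusion counts,
  tangency to exclusion never. These conventions are what make the
  exactly-once tiling property hold with circular profiles.
* **Poisson placement**, not fixed-N, so that density estimators are tested
  against the true rate including count fluctuations.
* **Guard margins**: disector grids inset 0.5 um in-plane and 4 sections in
  z by default, so profiles near the synthetic block's faces do not leak
  bias into the estimate. A small residual negative bias (about -1%) remains
  from rare very large objects truncated at the block faces; it sits well
  inside the 2% tolerance the recovery suite asserts.
* **Degenerate inputs**: zero densities yield empty (valid) tissue; all-equal
  volumes give $\sigma^2 = 0$ and $SE = 0$ with the goodness-of-fit p-values
  set to `NA`; constant responses in `lme_fit()` collapse to the OLS path and
  return the sample mean; empty point sets, non-positive geometry and
  malformed frames are rejected with messages.
* **Segmentation post-processing**: 26-connectivity for 3D components; the
  <1000-voxel filter and margin-overlap filter are the published QC rules.
  False splits are corrected by merging same-type components whose minimal
  voxel distance is below 2 voxels; candidate false *merges* (components far
  above the median size) are flagged in the report but not split
  automatically -- an automatic 3D watershed split would add a heavy
  dependency surface for a QC step whose published description is a single
  sentence, so the conservative flag-and-review contract was chosen instead.
* **Problem sizes in the validation suite**: the simulation tests use blocks
  of roughly 16-26 um per side (1,000-2,700 objects), 100-256 disectors and
  20-50 seeds per condition; these sizes put the Monte-Carlo error of each
  checked quantity comfortably below the asserted tolerance while keeping
  the suite desk-scale.

# Known limitations

* The disk proxy ignores curvature and perforation of real synaptic
  contacts; anisotropic deformation of an oriented disk is approximated
  (in-plane geometric mean for the diameter, z-factor for the cleft), exact
  for volumes and positions.
* The at-risk miss probability is an upper bound by construction; the
  package does not attempt to de-bias density estimates for misses (the
  bound is reported so users can judge whether a correction matters).
* `lme_fit()` reports Wald inference without small-sample df corrections
  (no Satterthwaite/Kenward-Roger); with few animals and dominant
  inter-animal variance its 2-SE intervals undercover, which is visible in
  the package's own recovery tests if the inter-animal share is made large.
* Real-data group values from the motivating study are not reproducible
  here (the raw EM volumes are not public); all quantitative claims in the
  test suite concern printed desk-scale arithmetic and behaviour on
  synthetic ground truth.

# A worked example

```{r example, eval = FALSE}
library(synstereo)

spec <- tissue_spec(box_dims = c(16, 16, 5.6), seed = 1)
factors <- deformation_factors(Re = 1.022^3, RX = 1.014, RY = 0.821, RZ = 0.985)
sim <- simulate_disector_experiment(spec, disector_grid_spec(),
                                    factors = factors, seed = 1)
sim$estimate    # wet-calibrated densities per mm^3
sim$jackknife   # percent symmetric with jackknife sd
```
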