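---
title: "Multi-level modelling of cleavage-stage cell lineages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level modelling of cleavage-stage cell lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastomere)
```

## The problem

Cleavage-stage embryos (the sea-urchin blastula is the motivating system)
develop from a small set of founder cells — at the 32-cell stage, 16
mesomeres (Mes), 8 macromeres (Mac), 4 large micromeres (LMic) and 4 small
micromeres (SMic), arranged in latitudinal bands from the animal to the
vegetal pole — through rounds of division with essentially no growth.
Automated light-sheet/two-photon reconstruction pipelines produce *digital
embryos*: a complete cell lineage tree in which every cell carries, at every
acquisition step (2–5 min), its position, volume, surface area and type
label. `blastomere` takes such tables and asks three questions:

1. How variable are individuals of a cohort, and how much of that
   variability is a trivial difference of developmental speed and egg size?
2. Can a small set of per-group probability laws reproduce the embryo-level
   dynamics — total cell number $N(t)$, total cellular volume $W(t)$, total
   surface $Z(t)$?
3. Do simple mechanical rules (adhesion, stiffness, an epithelial
   planarity constraint) suffice to shape those lineages into a spherical
   monolayered blastula with correctly placed territories?

## The statistical model

Cells are pooled into *groups* $g = (n, k)$ by generation rank $n$
(32-cell stage $=$ generation 6) and type $k$. Within a group, cells are
treated as exchangeable, and six per-cell features get idealised parametric
laws:

* cycle length $x_i$ and division time $m_i$: normal;
* cycle-averaged volume $\bar v_i$ and surface $\bar s_i$, and the
  daughter/mother ratios $a_i = \bar v_i / \bar v_{mother}$,
  $b_i = \bar s_i / \bar s_{mother}$: log-normal.

The *multi-level model* links groups across generations through three
recursions, with all increments independent:

$$M_g = M_{g-1} + X_g, \qquad
  \bar V_g = \bar V_{g-1} \cdot A_g, \qquad
  \bar S_g = \bar S_{g-1} \cdot B_g.$$

For normal laws, means and variances add; for log-normal laws the log-space
parameters add. A direct consequence — and the package's central testable
property — is that the variance of division times within a group equals the
initial variance plus the summed variances of all ancestor cycle lengths:
cell cycles desynchronise progressively, with no need for a mitotic
gradient or staged synchrony/asynchrony regimes.

Model fit is scored per final group and feature by the symmetrised
(Jeffreys) Kullback–Leibler divergence between the propagated and the
directly measured law, normalised by the cohort's internal variability (the
mean pairwise divergence between embryos for the same group and feature).
The *prototype* embryo is, per group and feature, the law minimising the
summed symmetrised divergence to the cohort members: a KL centroid. For
normal laws the optimal mean given $\sigma$ is a precision-weighted mean in
closed form, leaving a one-dimensional minimisation over $\sigma$
(`optimize()`), which the test suite checks against a brute-force grid
search.

## Rescaling

Embryos develop at different speeds from eggs of different sizes, so
cohort statistics are computed after an affine temporal alignment
$t \mapsto \beta t + \alpha$ and a linear spatial rescaling (volumes
$\times\gamma^3$, surfaces $\times\gamma^2$). Design choices, all in areas
where only "minimise the difference to the cohort mean" is prescribed:

* **Objective scale.** The temporal objective is L2 on $\log_2 N$. $N(t)$
  doubles once per generation; on the raw scale the last generations
  dominate the objective (they are 16 times larger), which leaves a long
  shallow valley trading $\alpha$ against $\beta$. On the log scale every
  division wave carries equal weight. The raw-scale objective remains
  available (`scale = "identity"`).
* **Alternation with a leave-one-out mean.** Each embryo is fitted against
  the average of the *other* embryos' rescaled curves, iterating to a fixed
  point (50 iterations max, change $< 10^{-4}$). Fitting against a mean
  that contains the embryo's own curve creates sticky spurious fixed
  points: the embryo can lock onto its own ghost in the average.
* **Plateau-aware search.** Step curves make the objective piecewise
  constant, so gradient methods are unreliable; the per-embryo fit is a
  three-level multiresolution grid search whose tie-breaking keeps the
  current point when it already attains the minimum and otherwise moves to
  the centre of the tied plateau. This makes an identical cohort an exact
  fixed point.
* **Gauge.** The cohort average is identifiable only up to a common affine
  map; embryo 1 is pinned to the identity.
* **Weighted spatial fit.** The residual spread of $W$ across a cohort is
  strongly time-dependent: tight early (egg volume), wandering later as
  per-division volume-ratio noise accumulates. The spatial fit is weighted
  least squares with inverse-variance weights estimated from the
  *scale-free* dispersion of $\log(W_i(t)/W_i(t_0))$ across embryos —
  independent of the $\gamma$ being estimated, hence no circularity.
* **$\alpha$ is reported but compared at the map level.** The intercept of
  an affine map fitted on a window 300–700 min away from $t = 0$ amplifies
  any $\beta$ noise by that lever arm. Recovery is therefore assessed on
  the fitted time *map* over the observation window (where it is accurate
  to about one acquisition step), not on the raw intercept.

## The synthetic cohort: a stated world

With the original five specimens unavailable offline, a generator replaces
them. Its defaults are a stated world, documented here once:

* 5 embryos, 32 typed founders, generations 6–10, acquisition step 2 min,
  full observation windows (30 min lead-in, 3-step tail).
* Cycle-length means rise from 40 to 90 min across generations 7–10 with
  standard deviations widening 4 to 10 min; micromeres cycle more slowly
  (LMic $\times 1.1$, SMic $\times 1.3$), macromeres slightly faster
  ($\times 0.95$). These are plausible placeholders for a cleavage-stage
  cohort, not measurements.
* Volume ratios are log-normal with *mean* 0.5 (log-mean
  $\log 0.5 - \sigma^2/2$, $\sigma = 0.18$, i.e. the reported $\pm 20\%$
  individual spread) so that total volume is conserved on average while
  sister volumes need not sum to the mother's; surface ratios are centred
  on the isometric $2^{-2/3}$ with $\sigma = 0.12$.
* Founder volumes: Mac 22000, Mes 12000, LMic 8000, SMic 3000 $\mu m^3$
  (log-sd 0.15), surfaces near the equivalent-sphere value (log-sd 0.10);
  root division times normal around 360 min (6 hpf), sd 6 min.
* Per-embryo distortions default to shifts of $-30\ldots+25$ min, speeds
  $0.88\ldots1.10$ and sizes $0.90\ldots1.12$, with embryo 1 the identity.

**Normalisation (`normalize_roots`).** The rescaling model assumes that,
after alignment, all embryos share one set of group laws — embryo-level
differences are *entirely* the affine/size distortions. Finite embryos
violate this by sampling: 32 founder draws leave the realised embryo mean
volume $\pm 2.7\%$, realised per-group cycle means drift $\pm 0.5$ min per
generation, and these endogenous offsets are then (correctly)
absorbed by the estimator, making "recovery of the injected parameters"
ill-posed. The generator therefore centres, per embryo: founder geometric
mean volumes/surfaces and founder mean division times per type, and each
(generation, type) group's cycle and log-ratio draws, on their law values.
Within-group spread — the object of all the statistics — is untouched. Set
`normalize_roots = FALSE` for fully unconstrained sampling.

What a green recovery test does **not** establish: the generator has no
positions (mechanics places them), no within-cycle volume dynamics (the
contraction/expansion phases of real $W(t)$ are out of model scope;
volumes are piecewise-constant at cycle means), no tracking errors, and no
type-dependent observation gaps. Features estimable only with a complete
cycle (cycle lengths, cycle-averaged geometry, ratios) are structurally
missing for founder cells and for the first generation's ratios — exactly
as in real windows — so root-generation geometric laws are asserted
*absent*, not recovered.

## Group statistics

Laws are fitted by moments (mean and unbiased sd, on logs for log-normal
features). Goodness of fit uses a chi-square test on equal-probability bins
under the fitted law, `max(5, floor(n/8))` bins, dof $=$ bins $- 3$;
eligibility needs $n \ge 8$ (configurable; the original analysis kept
about half of its 252 distributions for sample-size reasons without
stating the cut-off). Independence is reported as Pearson $R^2$ between
mother–daughter and sister–sister pairs, per group, with sisters ordered
randomly under a fixed seed (Pearson on unordered pairs is ill-defined).
The default features are the model's increments $x$, $a$, $b$: the
cascade-derived $m$, $\bar v$, $\bar s$ are dependent between relatives *by
construction* (they share the ancestral sum/product), so raw correlations
on them do not test the model's independence assumptions.

## Mechanics

Each cell is a particle with interaction radius $R_i = (3\bar v_i/4\pi)^{1/3}$,
an outward apicobasal axis (radial from the embryo centroid), and an
overdamped equation of motion $\lambda \dot x = F$. Pairwise forces act
between contacts ($r_{ij} < r_{max} = c_{max}(R_i+R_j)/2$, default
$c_{max} = 1.3$; equilibrium $r_{eq} = c_{eq}(R_i+R_j)/2$, $c_{eq} = 0.9$):

* attraction–repulsion along the pair axis: linear repulsion
  $\omega_{rep}(r_{eq}-r)/r_{eq}$ below $r_{eq}$; a single adhesive lobe
  $-4\,\omega_{adh}(r-r_{eq})(r_{max}-r)/(r_{max}-r_{eq})^2$ between
  $r_{eq}$ and $r_{max}$, zero at both ends, with homotypic
  ($\omega_{adh,o}$) or heterotypic ($\omega_{adh,e}$) coefficient;
* planarity conservation (the implicit blastocoel turgor support): for each
  contact, the pair separation is projected on the bisector of the two
  outward normals and pushed to zero with coefficient $k_{rig}$; it
  vanishes exactly for cells on a common sphere with radial axes.

The exact force profile of the original study is not public; this one
satisfies every stated constraint (zero at $r_{eq}$ and beyond $r_{max}$,
continuous, single adhesive hump) and is flagged as a substitution.

Numerics: the integrator is quasi-static — between division events the
configuration relaxes by explicit Euler steps with a per-step displacement
cap ($0.1 \times \min r_{eq}$) and an adaptive step that halves when the
force field reverses (the overshoot signature) and regrows while
descending. Divisions are batched per 2-min slice; daughters are placed
symmetrically about the mother, separated by $0.5\,r_{eq}$ along a
uniformly random direction in the tangent plane (hence exactly orthogonal
to the apicobasal axis). Everything is deterministic given (lineage,
parameters, seed).

Fixed coefficients were calibrated once so that the phase portrait falls
inside the swept adhesion range $[10, 1000]$, mirroring the original
study's choice of fixed repulsion and rigidity: $\omega_{rep} = 1000$,
$k_{rig} = 600$, $\lambda = 1$. A structural note: with a bounded repulsion
and a pairwise-local planarity force, uniform shell contraction is a
planarity zero mode, so the collapse transition is governed by adhesion
overwhelming repulsion (around $\omega_{adh} \approx 100\!-\!300$ under
division crowding) rather than by $k_{rig}$, whose role is resisting local
buckling. An explicit turgor-pressure term would change that balance; it is
out of scope here.

## Objective functions and the sweep

* Sphericity $S_s$: $1 -$ coefficient of variation of particle distances to
  the centroid, clipped to $[0,1]$.
* Planarity $P_s$: mean local coplanarity — per cell with $\ge 3$
  neighbours, $1 - 3\lambda_3/(\lambda_1+\lambda_2+\lambda_3)$ from the PCA
  of its neighbourhood; cells with fewer neighbours are skipped and
  counted.
* Border dissimilarity $D_s$ (Mic/Mac and Mac/Mes, micromere subtypes
  pooled): relative difference in heterotypic edge counts plus absolute
  difference in interface tortuosity (rms out-of-plane deviation of
  heterotypic edge midpoints from their best-fit plane, normalised by their
  in-plane spread) against a reference descriptor, by default the
  idealised latitudinal band layout.
* Combined fitness $w_1 S_s + w_2 P_s - w_3 D_s$, equal weights by default
  (the combination rule is not stated in the source analysis).

Phase labels: spherical–planar ($S_s > 0.9$, $P_s > 0.9$), collapsed
($P_s < 0.6$), polylobular ($P_s > 0.9$, $S_s < 0.7$), other. The best-fit
region is the spherical–planar subset reaching the upper fitness quartile.
On the default desk-scale sweep (5$\times$5 log-spaced grid, 3 replicates,
128-cell lineages) the best-fit mask sits at low heterotypic adhesion
with homotypic adhesion up to an order of magnitude larger, and the
high-adhesion corner collapses — the qualitative structure of the full
cluster-scale exploration, which remains reproducible via configuration.

## Known limitations

* Log-normal/normal families are imposed, not selected; the GOF report is
  descriptive.
* The KL centroid is computed per (group, feature); no smoothing across
  generations.
* The mechanical model is quasi-static and has no explicit blastocoel
  pressure, no cell shape beyond an interaction radius, and no
  division-plane bias; border sharpening arises from differential adhesion
  only.
* Degree columns (`d_i(t)`) join external contact graphs; the package does
  not segment membranes.
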