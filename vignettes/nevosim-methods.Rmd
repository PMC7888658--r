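---
title: "Models and methods behind nevosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nevosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nevosim simulates the growth of melanocytic nevi as an off-lattice
agent-based model on a geometric replica of the dermo-epidermal junction
(DEJ).  This vignette documents the models, the numerical choices, the
calibration of the shipped scenario presets, and what the synthetic-data
generators do and do not establish.

## The membrane as a composite manifold

The basal membrane is the surface on which (non-nested) melanocytes live.
It is modeled as a planar base plane at altitude zero (the base of the rete
ridges) from which dermal papillae protrude as surfaces of revolution, plus
an optional coarse vertical deformation field built from radially symmetric
bumps.

Each papilla is defined by a base radius $R$, a height $H$ and a scalar
shape parameter $p$.  Its lateral profile is a pair of quintic B-spline
components $\theta \mapsto (r(\theta), h(\theta))$ on $[0, R]$ with the
boundary conditions

$$r(0)=0,\; r(R)=R,\; r'(0)=r'(R)=1,\; r''=r'''=0 \text{ at } 0, R$$
$$h(0)=H,\; h(R)=0,\; h'=h''=h'''=0 \text{ at } 0, R,$$

so the surface of revolution joins the surrounding plane three times
continuously differentiably.  With ten control coefficients and four
uniform interior knots, these conditions pin the first and last four
coefficients; the two free interior vertices are displaced along the
$r$-axis by $0.15\,R\,p$ with $p \in [-1, 1]$.  Negative $p$ tapers the
papilla, positive $p$ broadens the top towards the shouldered and, at the
extreme, near-cylindrical type.  The admissible interval $[-1,1]$ is the
largest symmetric range for which the displaced control polygon remains
strictly increasing, which guarantees that $r$ is a strictly increasing
bijection and the surface is single-valued over the horizontal plane.

**Chart formulation.**  Rather than maintaining separate polar charts per
papilla with an explicit hand-off when a trajectory crosses a papilla rim,
nevosim uses a single global chart: outside papilla base disks the chart
coordinate is the horizontal position itself; inside the disk of a papilla
centred at $c$, the chart coordinate $u$ encodes the *virtual radius*
$\theta = |u - c|$, and the embedded surface point is
$c + r(\theta)\,\widehat{(u-c)}$ at altitude $h(\theta)$.  The induced
metric is

$$g(u) = E(\theta)\, \hat u \hat u^\top + (r(\theta)/\theta)^2 (I - \hat u
\hat u^\top), \qquad E = r'^2 + h'^2,$$

which the boundary conditions make $C^2$ across the rim
($E(R) = 1$, $E'(R) = 0$, $(r/\theta)^2 \to 1$) *and* at the apex (where
$r(\theta) = \theta + O(\theta^4)$ makes the metric flat to second order).
One geodesic ODE therefore integrates everywhere: no chart hand-off, no
polar coordinate singularity, and rim crossings are automatically $C^1$.
This is the package's main structural deviation from a per-chart design and
is the reason no apex fallback scheme is needed.

**Geodesic integration.**  Classic fourth-order Runge–Kutta on
$(u, \dot u)$ with Christoffel symbols assembled analytically from the
spline derivatives ($E$, $E'$, $r/\theta$ and its derivative).  The number
of substeps is chosen so each substep covers at most `max_substep`
(default 1 µm) of *surface* arc length — bounding the chart displacement
alone is insufficient where the metric is steep (meridional stretch up to
$\sqrt{E} \approx 3$–4 on tall papillae).  With this bound the surface
speed, which the exact flow conserves, is conserved to about $10^{-4}$
relative per step.  When the coarse deformation field is active at a
location, its Christoffel contribution is obtained by central finite
differences of the analytic metric (step $10^{-3}$ µm) instead of
propagating bump second derivatives analytically.

The coarse deformation is applied as a smooth additive altitude field
evaluated at the horizontal position.  A rigid per-papilla lift would break
the $C^1$ rim transition unless the field were locally constant; since the
bumps are an order of magnitude wider than papillae, the difference is
negligible while smoothness is preserved everywhere.

## Tissue synthesis

Shape statistics are fitted from section measurements (height, base
radius, radius at half height and at 10 µm below the tip).  All raw
section lengths are increased by 20% exactly once to compensate
dehydration shrinkage.  `fit_shape` fixes $H$ at the measured height and
fits $(R, p)$ by least squares on the three measured radii; `fit_distributions`
fits log-normal distributions to $R$ and $H$ and a beta distribution
(scaled to $[-1,1]$) to $p$, ignoring correlations.  The family assignment
(log-normal for strictly positive lengths, beta for the bounded shape
parameter) is a package choice; the sampler deliberately over-represents
the shouldered type via a mixture with a shoulder-skewed beta component
(default weight 0.6) so nests can form between papillae.

Packing places sampled base disks on a hexagonal lattice whose pitch
realizes the density target, then relaxes centre positions with annealed
pairwise push-apart moves (up to 500 rounds) and drops disks that cannot be
placed disjointly.  The two built-in presets are `"standard"`
(histology-scale papillae, target ≈130 mm⁻²) and `"large"`
(in-vivo-realistic papillae with base radius centred in 56–75 µm, target
≈60 mm⁻²); both land inside the 50–160 mm⁻² window that in vivo confocal
counting brackets once missing skin appendages are accounted for.

## Agent dynamics

Each melanocyte is a sphere with position, radius, generation number $g$,
inherited base proliferation rate $p_0$, and optionally a nest-strain
membership with its own within-strain generation $\gamma$.  The local
density is $\rho = \min(1, \sum_n \omega(d_n))$ over the 3D gap distances
to all other cells with $\omega(d) = 0.02\,(1 - d/100)^2$ on $[0, 100]$ µm
(the closed form is a package decision; maximum, decay order and support
are fixed by the model statement).  Per step of length $\Delta t$:

1. **Movement** (all cells): initial velocity $v^{(i)} = v_{\rm ext} +
   \sqrt{2 D Q(\rho) R(g)}\,\Delta t^{-1/2} z$; pairwise attraction within
   a strain and repulsion across strains ($v^{(ii)}$); collision
   correction ($v^{(iii)}$); then either a geodesic step on the membrane
   (default cells) or an unconstrained Euler step with dermal exclusion
   (nested cells).
2. **Division** with probability $\exp(A(g) B(\rho) p_0 \Delta t) - 1$;
   both daughters increment $g$, inherit size, position (with a symmetric
   offset) and $p_0$ with Gaussian noise ($\sigma = 0.01$, clamped at 0).
   A default-type division founds a new nest strain with probability
   $q_0$ (0.1 in globular scenarios), assigning the nested rate
   $p_0 = 0.1\,d^{-1}$.
3. **Emigration**: nested cells detach with probability
   $1 - e^{-s(\gamma)\Delta t}$, reattach to the membrane at their
   horizontal position and return to default behavior.
4. **Discard** of cells that left the domain (the only sink; there is no
   apoptosis).

The collision corrector subtracts, for every neighbor whose gap would not
absorb the projected advance, the excess projected component scaled by
$K$.  The neighbor sweep (ascending gap) is repeated to a fixpoint (at
most six passes): a single sweep lets corrections for one neighbor
reinstate the approach towards another, and in packed clusters that leaks
enough overlap to exceed a cell radius.  With the fixpoint sweep, interior
cells of a jammed cluster stay within ~1.5 µm of contact and their mean
displacement drops below 10% of a free cell's (the freezing effect), while
the corrector remains the paper-faithful velocity-space operation rather
than a physical contact solver.

Nested proliferation is damped by the within-strain senescence curve
$A_{\rm nest}(\gamma)$ but *not* by density ($B_{\rm nest} \equiv 1$ in
all presets): nests are modeled as highly proliferative and
density-insensitive, their size being controlled by strain senescence and
emigration.  This is what lets nests reach hundreds of cells despite
saturating the local density measure.

## Scenario presets and calibration

The exact control points of the damping curves and emigration curves are
not part of the model statement; they are package calibration, chosen to
reproduce the published aggregate outcomes, and recorded here:

* $A$: 1 up to a growth-arrest generation (35 or 45 depending on the
  scenario), declining to 0 at 60.
* $B$: 1 at low density declining to 0 at $\rho = 1$ (contact inhibition).
* $Q$: motility damping, 1 down to 0.02 at $\rho = 1$ (prevents jitter in
  packed regions; the strong value is needed for the freezing effect).
* $R$: motility declining to 0.3 at $g = 60$.
* Diffusivities: reticular scenarios use $D = 2$–3.5 µm² d⁻¹ — the scale
  implied by the printed reticular growth slopes; globular scenarios use
  $D = 30$ µm² d⁻¹ for the single-cell population: with slow diffusion the
  contact-inhibition halo around newly formed nests freezes the colonizing
  front and the lesion stalls, contradicting the observed globular growth.
* Globular strain curves: sharp within-strain senescence at $\gamma = 10$,
  and emigration rate curves $s(\gamma)$ starting at the base rate
  0.1 d⁻¹ that either decline quickly with $\gamma$ (scenarios 1–2,
  persisting nests) or stay level / increase (scenarios 3–4, dissolving
  nests, peripheral-rim morphology).

The strain curves were calibrated *against the deterministic
expected-nest-size recursion* (the aggregate model shipped as
`expected_nest_size`), not against simulation output: with division rate
0.1 d⁻¹ a nest needs ≈9.5 d per within-strain generation, so a senescence
cap at 9–10 generations yields peak sizes of a few hundred cells reached
at roughly 100 days — the published regime of 200–500 cells peaking at
about 100 d.  The stochastic engine reproduces the recursion because nest
demography is spatially unconfounded by construction
($B_{\rm nest} \equiv 1$).

## Aggregate oracle models

`expected_population` propagates generation-resolved expected counts:
generation $g$ loses its dividing mass at rate $e^{A(g) p_0 \Delta t} - 1$
and generation $g+1$ gains twice that mass.  As $\Delta t \to 0$ with
$A \equiv 1$ this reproduces $M_0 e^{p_0 t}$.  `expected_nest_size` is the
within-strain analogue with an additional multiplicative survival factor
$e^{-s(\gamma)\Delta t}$ per step.  Both are *unconditional* expectations:
a founder lineage that goes extinct contributes zero.  The replicate
statistic used for nest experiments (mean member count among replicates
whose nest still exists) is the survival-conditional version, consistent
with dissolved nests leaving the registry.

## Rendering

Dermatoscopy-style images are 10 µm positional histograms blurred with a
20 µm Gaussian and normalized by the 99.5th percentile — every melanocyte
radiates pigment radially symmetrically irrespective of depth, so these
images deliberately ignore translucency.  Histology-style sections draw
the membrane profile along a section line plus one disk per cell inside a
30 µm slab on a 1200 × 250 µm canvas.  Overhead diagnostic maps use fixed
scales (generation 0–60, altitude 0–200 µm) or one color per strain.
Bin width, blur width and palettes are package choices: the model
statement fixes only the histogram-blur-normalize pipeline.

## Synthetic data generators, and what a green test establishes

The supplementary measurement and growth tables behind the published
statistics are not redistributable, so the package ships *synthetic
stand-ins* with the same layout:

* `synth_measurement_table` draws papilla measurement tuples through the
  shape model and then affinely rescales the raw height/base-radius
  columns so the sample moments equal the published values exactly
  (59.7 ± 18.2 µm height, 28.0 ± 10.1 µm base radius, confocal density
  48.8 ± 5.29 mm⁻²).
* `synth_growth_table` draws 13 reticular and 25 globular lesions with
  per-lesion slopes recentred to the published group means (1.928e-3 and
  6.005e-3 mm² d⁻¹) and observation noise constructed orthogonal to time,
  so ordinary least squares recovers each slope exactly.

A green test on these fixtures establishes that the measurement-ingestion
and slope pipelines are correct, *not* that the model reproduces in-vivo
data: the in-vivo numbers enter as calibration targets, they are not
re-derived.  The simulation-side growth comparison (globular faster than
reticular, unpaired t-test) is computed from actual engine runs at reduced
scale.

## Numerical choices and degenerate inputs

* Geodesic substep bound 1 µm of surface arc; RK4; domain exit returns a
  signal and the caller discards the cell.
* Chart inversion (`chart_forward`) inverts the strictly monotone $r$ by
  safeguarded Newton to $10^{-11}$; off-surface points are rejected at a
  1e-3 µm altitude tolerance by default.
* Touching papilla base disks count as disjoint (open disks); the packing
  relaxation aims for a 0.5 µm clearance.
* Division probabilities above 1 (pathological $p_0 \Delta t$) raise an
  error rather than clamp.
* Zero-papilla membranes degenerate exactly to planar Euclidean
  kinematics; empty initial states produce empty trajectories.
* A single R random stream drives all stochastic processes; trajectories
  are reproducible from the master seed.  (Per-process named streams were
  considered and dropped: base R has no multi-stream API and determinism
  is the property that matters.)

## Known limitations

* Skin appendages are absent; papillae are rigid and never remodel.
* Intercellular forces are velocity-space heuristics; momentum is not
  conserved and deep transient overlaps of up to roughly one cell radius
  can occur in jammed regions within a single step.
* The full-scale published scenarios (5 × 5 mm, 1000–2500 d) take tens of
  minutes each; the shipped tests run reduced-scale versions and the
  growth-slope comparison is therefore a scaled qualitative reproduction,
  not a quantitative slope match.
* The dermatoscopic renderer has no depth-dependent translucency, so
  vertical structure (e.g. nests below the membrane) is visible only in
  the histology-style views.
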