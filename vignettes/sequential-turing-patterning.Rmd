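---
title: "Sequential masked Turing systems: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential masked Turing systems: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingbuds)
```

## The model

Feather primordia appear in waves: a first array of primary buds, then
ectopic buds at stereotyped positions around them once long-range
inhibition is relieved. `turingbuds` models this with $N$ independent
morphogen pairs $(u_i, v_i)$, $i = 1, \dots, N$ (default $N = 5$), each
obeying Schnakenberg activator–inhibitor kinetics gated by a competence
indicator $S_i$:

$$
\partial_t u_i = D_u \nabla^2 u_i + (a - u_i + u_i^2 v_i)\, S_i(x, y),
\qquad
\partial_t v_i = D_v \nabla^2 v_i + (b - u_i^2 v_i)\, S_i(x, y),
$$

on the rectangle $[0, 15] \times [0, 25]$, periodic in $y$ (top/bottom)
and zero-flux in $x$ (left/right): the patch stands for a small window of
a much larger tissue in $y$, bounded laterally in $x$. Morphogens diffuse
everywhere; reactions run only where $S_i = 1$, i.e. in tissue not yet
patterned. System 1 is competent everywhere and integrates for 500 time
units; each subsequent system integrates for 1,000 time units on the
domain minus the dilated condensations of all previous systems. The pairs
interact *only* through this geometry — there is no kinetic coupling
between systems, and each system starts from its own freshly perturbed
homogeneous state, because the morphogen pairs are treated as distinct
species that interact in the same way.

Key modelling assumptions, stated explicitly:

* **Phenomenological competence.** "Patterned" tissue is defined by
  thresholding the activator; no mechanics, growth, or cell movement.
* **No built-in anterior–posterior asymmetry.** The anterior–posterior
  axis is assigned to the periodic $y$ direction only after simulation, so
  mirror-image outcomes are equally likely by construction.
* **Constant diffusivities.** The gate multiplies only the kinetics.
  (A configuration hook exists to slow diffusion inside patterned regions,
  default off; the canonical scenarios never use it.)

## Linear stability analysis

The homogeneous steady state is $u^* = a + b$, $v^* = b/(a+b)^2$. A
perturbation $\propto e^{\lambda t + i k \cdot x}$ grows at the largest
real eigenvalue of $J - k^2\,\mathrm{diag}(D_u, D_v)$, where $J$ is the
kinetic Jacobian at $(u^*, v^*)$; `dispersion_relation()` evaluates this
via the closed-form $2 \times 2$ characteristic polynomial (exact and
cheaply testable, rather than a general eigensolver). Turing instability
requires $\mathrm{tr}\,J < 0 < \det J$ together with a band of unstable
$k > 0$; the marginal condition
$D_v f_u + D_u g_v = 2\sqrt{D_u D_v \det J}$ gives the critical ratio
$d_c = D_v/D_u$. For $a = 0.3$, $b = 0.8$: $u^* = 1.1$,
$\mathrm{tr} J \approx -0.755$, $\det J = 1.21$, and $d_c \approx 28.5$.

```{r dispersion}
p <- kinetic_params()
d <- dispersion_relation(p, k_max = 1.5, n_samples = 601)
d$d_crit
2 * pi / d$k_crit   # fastest-growing wavelength
```

**Choice of diffusivities.** Only the kinetic constants are canonical; the
diffusion coefficients are stated to be positive constants without values.
We default to $D_u = 1$, $D_v = 40$ — comfortably above $d_c \approx 28.5$
so the spot-forming regime is guaranteed, with a fastest-growing
wavelength $2\pi/k_c \approx 15$ comparable to the domain width, so the
first system produces the main large spot structure (a few primary spots,
not a fine dot lattice). Both are configurable per system; all five
systems default to identical parameters because nothing in the model
requires later systems to differ — the spatial restriction alone shrinks
the patterns.

On the rectangle, admissible perturbations are cosine modes
$k_x = \pi p / 15$ (zero-flux) combined with integer modes
$k_y = 2\pi m / 25$ (periodic); `dispersion_relation(..., grid = )`
reports the admissible mode nearest to the continuous maximiser.

## Numerical scheme

Space is discretised with the 5-point Laplacian on a uniform staggered
grid (cell centers at $(i + \tfrac12)h$), default $120 \times 200$ cells
(spacing $0.125$, about 120 cells per pattern wavelength), mirror ghost
cells in $x$ and wrap-around in $y$. Time stepping is a
Peaceman–Rachford alternating-direction (ADI) semi-implicit step, default
$\Delta t = 0.05$: each half-step treats one diffusion direction
implicitly (constant-coefficient tridiagonal solves — Thomas in $x$,
Sherman–Morrison cyclic Thomas in $y$, with factors precomputed once) and
the gated kinetics explicitly. A fully explicit Euler scheme is included
as an independent reference for cross-checks; it is only stable for
$\Delta t \lesssim h^2 / (4 D_v)$ and is used on small problems.

Two properties drove this choice:

* **Unconditional diffusion stability**, so $\Delta t$ is set by the
  $O(1)$ kinetic time scale, not by $D_v / h^2$.
* **Second-order splitting whose stationary states satisfy the discrete
  balance to $O(\Delta t^2)$.** This matters more than transient accuracy
  here: a simpler sequential (Lie) split of backward-Euler solves leaves
  an $O(\Delta t\, D^2)$ defect in the *stationary* pattern, which at
  $D_v = 40$ is large enough to displace spots and even flip
  near-degenerate arrangements between $\Delta t$ levels. With the
  Peaceman–Rachford step the intermediate state differs from the final
  one by $O(\Delta t \times \text{stationary residual})$, so converged
  patterns are insensitive to $\Delta t$ (halving $\Delta t$ moves the
  converged field by $\sim 10^{-4}$ in relative max-norm, and seeded
  Fourier modes grow within 1% of their closed-form rates).

Both implicit operators conserve mass exactly (zero row sums, direct
solves), so with $S \equiv 0$ the spatial integral of each species is
preserved to rounding over arbitrarily many steps. The implicit solves are
additionally *deflated* against a reference constant (the operator maps
constants to themselves exactly, so only the deviation is swept): this
makes spatially uniform states bit-exact fixed points of the scheme.
Without it, per-position rounding in the sweeps ($\sim 10^{-16}$) seeds
non-uniform modes that a Turing-unstable run amplifies by
$e^{\lambda_{\max} t}$ — about $4 \times 10^{14}$ over 500 time units —
turning the homogeneous steady state into a visibly patterned field with
no applied perturbation. Concentrations are
allowed to undershoot zero by at most $10^{-9}$ (explicit kinetics can
transiently round below zero); anything more negative, or non-finite,
aborts the run with the offending time and cell.

"Reached stability" is operationalised as the fixed schedule (500, then
1,000 time units each) — matching the stated protocol — with a
convergence flag (final $\max |\Delta \text{field}| / \Delta t <
10^{-4}$) logged but not gating. At the defaults all systems converge
well before their allotted time.

## Condensations and competence masks

A **condensation** is a connected component (4-connectivity, wrapping
across the periodic $y$ seam) of cells with
$u > u^* + \theta\,(\max u - u^*)$, at least 4 cells in size. The
threshold fraction $\theta = 0.5$ (half-maximum above steady state) is
scale-free and robust to overall amplitude; "condensation" is never
defined quantitatively in qualitative accounts of such models, so this is
a stated package decision, as is the 4-cell floor (suppresses single-cell
noise) and the 4-connectivity (conservative splitting of near-touching
spots).

**Membership is restricted to competent cells.** Outside $\Omega_i$ the
gated equations have no degradation term, so activator diffusing out of a
forming bud relaxes to a harmonic plateau over the excluded tissue and
can exceed the threshold there. Biologically a bud is a cellular
aggregate of competent tissue; activator sitting in already-differentiated
tissue is residual morphogen, not bud. `extract_condensations()` therefore
intersects the above-threshold set with the system's own mask, which also
guarantees the invariant that no condensation overlaps excluded tissue.

The next mask is the previous one minus every condensation dilated by a
disc of radius 0.5 length units (periodic in $y$). The margin reflects
that patterned regions visibly exceed the bright spot cores; it is a
configuration knob.

**Scenarios.**

* `full` — every earlier system restricts the next; masks shrink
  monotonically.
* `remove_bud2` — system 2 still runs, but its condensations are never
  excluded from later masks (its spatial influence is removed, the bud
  itself still exists).
* `horseshoe` — systems 3+ are confined to
  `AND(system-1 exclusions, ring)` where the ring is centred on the
  primary spot with inner radius $1.2\times$ the primary-spot radius,
  width 2.5 length units, and a $60°$ half-angle opening facing posterior
  ($+y$). The radii and angles are package decisions (no quantitative
  geometry is published for the crescent-shaped competent area); the
  opening faces posterior because no ectopic buds are observed immediately
  posterior to primary buds. The ring must fit within half the periodic
  extent, or it would self-overlap through the wrap.

Per-system noise seeds are drawn deterministically from the schedule seed,
so a run is bit-reproducible from `(schedule, grid, settings)`.

## Spot metrics and the positional taxonomy

`detect_spots()` pools per-system condensations; the primary bud is the
largest-area system-1 spot. Ectopic spots are classified relative to the
primary by distance and bearing (bearing 0° = anterior = $-y$, positive
toward $+x$):

| class | rule |
|---|---|
| 2 (interbud) | distance > interbud radius |
| 3 (anterior) | bearing in $[-30°, 30°)$ |
| 4 / 4′ (lateral right/left) | $\pm[30°, 90°)$ |
| 5 / 5′ (posterior-lateral) | $\pm[90°, 150°)$ |
| unclassified (posterior) | remaining $60°$ wedge |

The sector boundaries are half-open and configurable; the symmetric
partition matches the reported layout of ectopic positions, and the
posterior wedge is deliberately unlabelled because ectopic buds are not
observed there. The interbud radius defaults to $0.6\times$ the system-1
nearest-neighbour spacing (or $0.6 \times \min(\text{extents})/2$ when
only one primary spot exists) — the interbud position is defined only as
"maximal distance from adjacent primary buds", so the 0.6 factor is a
package decision. Right versus left (4 vs 4′) is the sign of the $x$
offset. Classified sets collapse to canonical combination codes
(`"1+2+3+4'"`); `unclassified` is not part of the vocabulary.

All distances use the periodic $y$ metric (two spots at $y = 5$ and
$y = 24$ on the 25-period are 6 apart, not 19).

## Synthetic fixtures

`generate_fixture()` produces every input the pipeline's tests need,
without external data: seeded perturbed-homogeneous Turing initial
conditions; planted isotropic Gaussian bumps (truncated at $4\sigma$ so
they are compactly supported and trivially integrable) with their centers
as ground truth; hexagonal spot lattices commensurate with the periodic
$y$ extent; and single admissible Fourier modes with their exact discrete
Laplacian eigenvalue. These fixtures emulate the *geometry* of patterns —
they do not emulate microscopy, experimental noise, tissue growth, or the
anisotropies of real skin, so passing tests demonstrate correctness of
the model implementation, not fidelity to real explants.

## Problem sizes used by the test suite

Unit tests run on grids from $30 \times 50$ to $120 \times 200$. The
end-to-end property checks use the package's two standard desk scales:
the canonical $120 \times 200$ grid for the showcase full run and the
refinement comparison (against $240 \times 400$ with $\Delta t$ halved),
and a $60 \times 100$ grid (spacing 0.25, still 60 cells per wavelength)
for multi-seed sweeps — e.g. the anterior/posterior symmetry check runs
the first two systems of the full scenario across 20 seeds at that
resolution.

## Known limitations

* **Late-system positions are near-degenerate.** Systems 3–5 pattern in
  narrow leftover corridors where several spot arrangements have almost
  equal energy. The *number* of spots in the final composite pattern is
  robust to refinement (halving both $h$ and $\Delta t$ preserves it, and
  early-system spots reproduce to $\sim 0.25$–$0.5$ length units), but
  individual late spots can relocate by a few length units or condense
  one system later, because $O(h^2)$ differences in the rasterised masks
  tip the degeneracy. This is a property of the model class, not of the
  integrator.
* **Mode quantisation.** On the $15 \times 25$ domain the fastest-growing
  wavelength ($\approx 15$) is comparable to the domain, so measured spot
  spacings sit on admissible modes and can deviate from $2\pi/k_c$ by
  $\sim 10\text{–}20\%$.
* **No directional bias.** Because the model adds no anterior–posterior
  asymmetry, ensemble statistics over seeds place bud 2 on either side of
  the primary bud; individual runs are not comparable to an oriented
  embryo without post hoc axis assignment.
* The competence rule is purely geometric; no account is taken of tissue
  mechanics, proliferation, or the slower diffusion plausibly associated
  with differentiated tissue (hook present, off by default).
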