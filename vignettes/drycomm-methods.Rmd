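---
title: "Methods: trait-structured vegetation patterning and community assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-structured vegetation patterning and community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`drycomm` simulates a water-limited plant community structured by a
single tradeoff trait $\chi \in (0, 1]$: investment in shoot growth
($\chi \to 0$: high light-capture capacity $K$, high mortality $M$,
high contribution $Y$ to soil infiltration) versus investment in
tolerating water stress ($\chi \to 1$: low $K$, $M$, $Y$).  The species
pool is discretised into $N$ functional groups, $\chi_i = i/N$, with
per-bin above-ground biomass densities $B_i(x,t)$, coupled to soil
water $W(x,t)$ and surface water $H(x,t)$ (all kg/m$^2$) on a periodic
one-dimensional domain:

$$\partial_t B_i = \Lambda_i W B_i - M_i B_i
  + D_B \partial_x^2 B_i + D_\chi \partial_\chi^2 B_i,$$
$$\partial_t W = I H - L W - \Gamma W \bar B + D_W \partial_x^2 W,$$
$$\partial_t H = P - I H + D_H \partial_x (H^\alpha \partial_x H),$$

with $\bar B = \sum_j B_j$, $\bar{\bar B} = \sum_j Y_j B_j$ and local
rates

$$\Lambda_i = \frac{\Lambda_0 K_i}{\bar B + K_i}, \qquad
  I = A\,\frac{\bar{\bar B} + f Q}{\bar{\bar B} + Q}, \qquad
  L = \frac{L_0}{1 + R \bar B}.$$

Growth saturates with total biomass (competition for light, including
self-shading); infiltration of surface water rises from $fA$ on bare
soil to $A$ under dense vegetation (differential infiltration, the
scale-dependent feedback that destabilises uniform vegetation);
evaporation is reduced by shading.  Traits follow linear tradeoffs,
e.g. $K(\chi) = K_{max} + \chi (K_{min} - K_{max})$.  The trait
derivative is the discrete second difference
$N^2 (B_{i+1} - 2 B_i + B_{i-1})$, a minimal model of mutations into
neighbouring groups at rate $D_\chi$.

Precipitation $P$ is stated in mm/y; 1 mm of rain on 1 m$^2$ weighs
1 kg, so mm/y and kg/(m$^2$y) are interchangeable and the equations are
used in that identification throughout.

Defaults (see `dc_params()`) describe a drybush/grassland-like system:
$\Lambda_0 = 0.032$ m$^2$/(kg y), $\Gamma = 20$ m$^2$/(kg y),
$f = 0.01$, $A = 40$/y, $Q = 0.06$ kg/m$^2$, $L_0 = 4$/y,
$R = 10$ m$^2$/kg, $K \in [0.1, 0.6]$ kg/m$^2$, $M \in [0.5, 0.9]$/y,
$Y \in [0.5, 1.5]$, $N = 128$, $D_B = 1$, $D_W = 10^2$,
$D_H = 10^4$ m$^2$/y, $D_\chi = 10^{-6}$/y, $\alpha = 0$ (linear
overland flow).  The six-orders-of-magnitude gap between $D_H$ and
$D_\chi$ is the defining numerical difficulty: hydrology relaxes in
days, the mutation–selection balance in $\sim 1/D_\chi = 10^6$ y.

## Boundary conditions and conservation

Space is periodic.  In trait space we use zero-flux conditions realised
by *reflecting ghost bins* ($B_0 = B_1$, $B_{N+1} = B_N$), which makes
the discrete trait diffusion operator conserve total biomass exactly
(its output sums to zero, to machine precision).  The per-bin biomass
$B_i$ is the biomass of a $\Delta\chi = 1/N$ trait bin, not a
trait-space density; the density view $b_i = N B_i$ is the
representation whose amplitude does not change with $N$.

## Solvers

*Spatially decoupled (mean-field) model* — `integrate_uniform()` runs
the $N + 2$ rate equations with `deSolve::lsoda` (adaptive,
stiff-capable), sampling time geometrically from 1 y to the horizon.
Steadiness requires $\max_i |\dot B_i| < 10^{-9} \max_i B_i$ *and* a
minimum horizon of $10/D_\chi$ years when $D_\chi > 0$ — distributions
can look stationary on ecological time scales while still drifting
along the trait axis on mutational ones.  The default horizon is
$10^7$ y; with BDF steps growing near the equilibrium this costs only
seconds at $N = 128$.

*Spatial model* — `integrate_spatial()` uses `deSolve::lsodes` with
numerically detected Jacobian sparsity.  The Jacobian couples all
$N + 2$ fields locally (dense trait blocks through $\bar B$ and
$\bar{\bar B}$) plus nearest spatial neighbours including the periodic
wrap; the sparse BDF factorisation handles the stiff surface-water
diffusion implicitly and takes very large steps once fronts stop
moving.  Operator-splitting schemes were rejected: the Turing growth
rate ($\sim 10^{-2}$/y) is a small residual of large opposing terms
($|IH|, |D_H k^2 H| \sim 10$–$10^2$/y), and the splitting error of a
first- or second-order split at any affordable step overwhelms it —
measured growth rates even changed sign.  Tiny negative undershoots
(below $10^{-10}$) from the BDF interpolant are clipped; anything
larger aborts the run.

*Linear stability* — the single-group model (all bins empty except
one) has equilibria found by a sign-change scan plus root polishing on
the scalar water balance; the bare-soil state $(0, P/L_0, P/(fA))$ is
exact at every $P$.  `dispersion_relation()` evaluates the largest
eigenvalue real part of the $3\times3$ reaction Jacobian minus
$k^2\,\mathrm{diag}(D_B, D_W, D_H)$ over 200 log-spaced wavenumbers
(wavelengths 5–500 m) with golden-section refinement of the maximum;
`turing_point()` bisects precipitation until the maximal growth rate
crosses zero ($|\sigma_c| < 10^{-8}$).  For the stress-tolerant group
($\chi = 1$) this gives $P_T = 92.95$ mm/y and a critical wavelength
$2\pi/k_c = 75.7$ m; the bare-soil instability threshold has the
closed form $P_B(\chi) = M(\chi) L_0 / \Lambda_0$ (62.5 mm/y at
$\chi = 1$, 112.5 at $\chi = 0$).

## Diversity metrics

Community composition is summarised by $\chi_{max}$ (modal trait, ties
broken toward lower $\chi$), functional richness $FR$ (width in $\chi$
of the region where the distribution exceeds a small "seedling"
threshold, edges linearly interpolated between bins), the Shannon
analogue $H' = -\sum_i b_i \ln b_i$ on biomass shares, and Pielou
evenness $FE = H'/\ln N$ with the full grid size $N$ (zero bins
included, as the definition states).

The richness threshold is referred to the **trait-space density**
$b = N B$ (default $10^{-3}$ kg/m$^2$ per unit trait).  This is a
deliberate design decision: a threshold on the per-bin biomass makes
$FR$ shrink as $\log N$ (per-bin amplitudes scale as $1/N$), whereas
on the density scale $FR$, like $\chi_{max}$, is practically
independent of $N$ — the property the metric set is meant to have.
`functional_richness(..., density = FALSE)` restores the per-bin
convention.  $FR$ retains an irreducible threshold sensitivity of
roughly 0.05 per decade of threshold (quantified by
`analysis/03_downshift.R`), which is why richness comparisons in the
tests carry $\pm 0.04$ bands.

Note that $FE$ is *not* $N$-independent: for a fixed smooth shape
$H' = \ln N + \text{const}$, so $FE = 1 - c/\ln N$.  Evenness values
are therefore only comparable at equal $N$; all reported $FE$ values
use $N = 128$.

## Initial conditions and experiments

All community runs start with **every functional group present**, by
default at a floor of $10^{-3}$ kg/m$^2$ per bin (long-lived seeds);
the asymptotic community is insensitive to the floor (tested across
$10^{-6}$–$10^{-3}$).  Spatial noise is multiplicative, uniform,
seeded, and applied to biomass only.

The experiment drivers under `analysis/` reproduce the study's
computational experiments:

1. *Emergence* (`run_emergence`): at $P = 180$, $D_\chi = 0$ yields
   competitive exclusion (a single surviving bin); $D_\chi = 10^{-6}$
   yields a stationary hump — the emergent community.
2. *Downshift* (`run_downshift`): stages 150 → 100 → 80 mm/y, each
   seeded from the previous asymptote.  Stages above the $\chi = 1$
   Turing threshold (92.95 mm/y) use the decoupled model; below it the
   spatial model runs from the uniform distribution plus $10^{-2}$
   seeded noise.  The patterned community at 80 shifts *back* toward
   growth-investing traits ($\chi_{max}$ 0.77 → 0.66) with higher
   richness and ~50% more biomass than the (unstable) uniform
   equilibrium at the same rainfall.
3. *Buffering* (`run_buffering`): sweeping a patterned state further
   down in $P$, composition and richness stay nearly constant while
   patches thin, until patch elimination or collapse.
4. *Hybrids* (`run_hybrid`): at $P = 100$ (inside the
   uniform/patterned bistability range) composites of converged
   patterned and uniform states relax to stationary hybrids with
   pinned fronts.

Hybrid initial states deserve a note.  The generator
(`make_initial(kind = "hybrid")`) builds a raised-cosine modulated
subdomain, but relaxing that rough construction is expensive — the
stiff solver must resolve the front-sharpening transient and the slow
front creep that follows.  `run_hybrid()` therefore splices
*converged* patterned and uniform states (the patterned template is
grown from the Turing instability at lower $P$, then continued at the
target $P$), which is both cheaper and closer to the idea of composing
coexisting stable states.  Front pinning is verified a posteriori: the
patterned/uniform domain mask (local relative standard deviation of
$\bar B$ over a one-wavelength window above 0.1) must move by at most
2 cells over the final quarter of the run.

Two caveats from the time-integration approach.  First, the spliced
fractions drift before the fronts pin (initial patterned fractions
0.25/0.5 settle near 0.52/0.86 of the domain), so the achieved domain
proportions, not the requested ones, are reported.  Second,
time-integrated hybrids sample only the attractor a given composite
falls into, not the full ladder of hybrid states a continuation method
would trace; the evenness spread across our two hybrids is accordingly
much smaller than the spread across the hybrid family proper.

## Problem sizes and numerical choices

The default experiment sizes are the reference conditions: $N = 128$
groups, spatial domain of 4 critical wavelengths ($\approx 303$ m)
with 128 cells ($\approx 2.4$ m spacing, 32 cells per wavelength;
at least 20 per wavelength is enforced by a warning).  An
integer number of wavelengths is required so periodic boundaries admit
the critical mode; hybrid subdomains are quantised to whole
wavelengths for the same reason.  Mean-field horizons are $10^7$ y
(the $10/D_\chi$ rule); spatial stages run $2\times10^5$ y, which the
BDF residual check confirms is deep into the stationary regime.  Unit
and property tests run the same code at reduced size ($N = 16$–64,
2 wavelengths) where the property under test permits.

Solver tolerances: `lsoda` at rtol $10^{-8}$/atol $10^{-14}$
(mean-field), `lsodes` at rtol $10^{-6}$/atol $10^{-12}$ (spatial);
halving either changes the headline metrics by far less than one trait
bin.  Wavelength detection uses the dominant non-zero Fourier mode of
$\bar B(x)$ with a relative contrast threshold of $10^{-3}$ separating
"patterned" from "uniform".

## What the generator emulates — and what it does not

Initial-condition generation plus the deterministic PDE stand in for
field data here; every reported number is a property of the model's
attractors under the stated parameters.  The model omits, among other
things: demographic stochasticity and seed dispersal kernels,
rainfall intermittency (P is a constant flux), terrain slope (no
advection of $H$), two-dimensional pattern morphologies (gaps,
labyrinths, spots), soil heterogeneity, and any trait dependence of
mortality on soil moisture.  Passing tests therefore demonstrate
internal consistency of the mechanism — differential infiltration
driving patterning, patterning reshaping community structure — not
quantitative agreement with any particular field system.

## Known limitations

* Stability of branches is assessed by perturbed time integration;
  unstable solution branches (and the snaking ladder of hybrid states)
  are invisible to this method, so bifurcation diagrams traced by
  `trace_branch()` show stable segments only.
* Wavelength selection from noise is domain-quantised; just below the
  Turing point the critical mode wins, but deeper in the unstable
  range neighbouring modes (e.g. 3 vs 4 bumps per domain) can be
  selected depending on the noise seed.
* At $P$ values approaching the fold of the vegetated branch the
  root-finding scan can miss closely spaced roots; the scan uses 4000
  points on $[0, 2]$ kg/m$^2$, ample for the default parameters.
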