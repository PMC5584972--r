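---
title: "Models and metrics for mutualistic range expansions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and metrics for mutualistic range expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperfront)
```

# The system

`hyperfront` models a pair of engineered *E. coli* auxotrophs that feed each
other an amino acid — an isoleucine auxotroph I⁻ that secretes leucine and a
leucine auxotroph L⁻ that secretes isoleucine — together with a parasitic
strain P that consumes a cross-fed amino acid without reciprocating, but can
detoxify ampicillin by secreting beta-lactamase. Because each mutualist's
growth requires the other's product, the pair behaves like a two-member
hypercycle: growth is second order in the densities, so neither strain can
proliferate alone. The package provides four model layers and the statistics
used to quantify colony range expansions.

# Well-mixed dynamics

The two-member hypercycle is

$$\frac{d\Phi_1}{dt} = \alpha_{12}\,\Phi_1\Phi_2
  \Big(1-\frac{\Phi_1+\Phi_2}{K}\Big) - \delta_1\Phi_1,$$

and symmetrically for $\Phi_2$. Death rates default to zero — the logistic
term already caps growth, and no independent estimate of the $\delta_i$ is
available — but are accepted as parameters. The three-strain community adds
a parasite with a single cross term to its donor mutualist and the shared
logistic bracket,

$$\frac{dP}{dt} = (\mu_P P + \alpha_P\,P\cdot \mathrm{donor})
 \Big(1-\frac{N}{k}\Big), \qquad N = I + L + P .$$

This is the minimal form consistent with the two-species structure; no
published three-species equations exist for this system, so the donor is a
configuration choice. The default donor is I⁻ (P consumes the leucine that
I⁻ secretes), matching the sensing assignment of the lattice model below;
the experimental description of P as an isoleucine consumer corresponds to
`donor = "L"`, and both are supported.

Integration uses `deSolve::lsoda` with absolute tolerance $10^{-9}$ and
relative tolerance $10^{-7}$; the kinetics are non-stiff at the parameter
scales of interest, and the test suite cross-checks trajectories against an
independent fixed-step RK4 integrator at $dt = 10^{-4}$.

Rate inference mirrors plate-reader practice. Malthusian rates come from an
OLS fit of $\log(\text{signal} - \text{background})$ against time over a
user-chosen exponential window. Hyperbolic (cross-catalytic) rates use the
low-density approximation $dI/dt \approx \alpha_{IL} I L$: the
finite-difference derivative (central differences on interior points, second
order without smoothing assumptions) is regressed through the origin on the
density product. A guard refuses windows where $\max(I+L)/k$ exceeds 0.1 by
default, since the neglected logistic factor then biases the estimate.
Fluorescence converts to density linearly, with the background clamped at
zero.

# Front theory

With diffusion added, the obligate pair ($\mu_i = 0$) invades as a
*pushed* front. In dimensionless variables (densities over $k$, time scaled
by $\alpha_{IL}k$, space by $\sqrt{\alpha_{IL}k/D}$) the system depends only
on $\alpha^* = \alpha_{LI}/\alpha_{IL}$. The reciprocal-power ansatz

$$U_i(z) = \frac{\xi_i}{(1 + a e^{bz})^s}, \qquad z = r - ct$$

turns each PDE into an identity in $z$. Clearing the common factor
$\eta^{-(s+2)}$, $\eta = 1 + ae^{bz}$, leaves terms proportional to $e^{2bz}$,
$e^{bz}\eta$, $\eta^{2-s}$ and $\eta^{2-2s}$. For the identity to hold at all
$z$ the coefficient attached to each distinct power must vanish. When $2-s$
and $2-2s$ are non-negative integers the $\eta$ powers fold into the
polynomial part and cancellation is possible; otherwise some group has a
strictly positive coefficient and no positive solution exists. That forces
$s = 1$, and then the groups yield $b = c$, $\xi_I + \xi_L = 1$,
$\xi_L = 2c^2$ and $\alpha^*\xi_I = 2c^2$, hence

$$\varepsilon_I = \frac{1}{1+\alpha^*}, \quad
  \varepsilon_L = \frac{\alpha^*}{1+\alpha^*}, \quad
  c = \sqrt{\frac{\alpha^*}{2(1+\alpha^*)}},$$

and in dimensional units
$v = \sqrt{Dk\,\alpha_{IL}\alpha_{LI} / (2(\alpha_{IL}+\alpha_{LI}))}$.
`characteristic_residuals()` exposes the coefficient groups for any
candidate, `wave_residual_at()` checks them independently by direct numeric
substitution at sampled $z$, and `find_wave_exponent()` scans candidate
exponents by minimising the squared groups over positive $(\xi_L, b, c)$
(gauge $a = 1$; the offset is pure translation), polished by Gauss-Newton:
only $s = 1$ reaches residuals below $10^{-10}$.

Two remarks on the printed formulas this package had to interpret. First,
the dimensionless ratio is taken as $\alpha^* = \alpha_{LI}/\alpha_{IL}$;
a carrying-capacity factor sometimes attached to it is dimensionally
inconsistent and incompatible with the dimensional speed formula, which both
definitions must reproduce. Second, the intermediate relations are
$c = \sqrt{\varepsilon_L/2}$ and $c = \sqrt{\alpha^*\varepsilon_I/2}$ (the
radicals are required for the final speed expression to follow).

# The reaction–diffusion solver

`simulate_rd()` integrates the planar 1-D system (a radial Laplacian in
flux form is available for finite-radius studies; the asymptotic front
discards curvature). Space is discretised by central differences with
no-flux boundaries written in flux form, so diffusion conserves mass to
round-off. Time stepping is classical RK4 on the semi-discrete system
rather than forward Euler: the package asserts agreement with the
well-mixed ODE limit to $10^{-6}$ relative, which first-order time stepping
cannot reach at any practical step size, while RK4 attains it at the same
CFL-guarded step ($D\,\Delta t/\Delta x^2 \le 0.25$, checked, with a
suggested step in the error message).

The default initial condition is a step of height
$k\,(\varepsilon_I, \varepsilon_L)$ on $r \in [0, r_0]$: seeding at the
asymptotic bulk composition makes the pushed front converge within a few
diffusion times. Front positions are the outermost threshold crossings with
linear sub-grid interpolation; the default threshold is half of $k$, which
suits single-species fronts, while two-species measurements pass a quarter
of $k$ explicitly because each species' bulk plateau is only a fraction of
$k$ ($k/2$ each in the symmetric case). Speeds are OLS slopes over the
trailing half of the trace. Pushed fronts converge exponentially fast and
are tested at 3% against the closed form; pulled (Fisher) fronts converge
like $1/t$ and are tested at 5%.

`speed_vs_mu_sweep()` interpolates between the obligate and competition
regimes by scaling the two Malthusian caps
($\mu_{CI} = 9.13\times10^{-2}$, $\mu_{CL} = 2.18\times10^{-1}$ hr⁻¹, the
observed monoculture rates) by a common fraction on top of fixed cross
terms. The sweep reproduces the transition shape: equal coupled speeds at
the obligate point (the minimum), then branch splitting with the faster
L⁻ strain escaping toward its Fisher speed while I⁻ falls behind. The
sweep's domain size, duration and front definition are package choices
(declared defaults), so the transition is reproduced as a shape, not
point-by-point.

# The lattice colony model

The agent-based simulator keeps the threshold (Heaviside) cell logic on a
square lattice with site exclusion (one cell per site) and five diffusing
fields: food, the two amino acids, ampicillin and beta-lactamase. Each
sweep applies sense → exchange → field transport → division with a single
seeded generator; cell order in the division pass is reshuffled every step
to avoid directional artifacts, and runs are bit-reproducible from the
seed.

* **Sensing.** A cell may grow only if local food exceeds $g_f$, its
  strain's amino acid (iso for I⁻; leu for L⁻ and P) exceeds $g_{am}$, and
  antibiotic is strictly below $g_{at}$ — "exceeds"/"below" are implemented
  as strict inequalities, so a field exactly at threshold blocks growth.
* **Exchange.** Cells with food above $g_f$ absorb food and secrete their
  product (I⁻ → leu, L⁻ → iso, P → enzyme) at constant rates; cells
  passing the full gate also absorb their required amino acid. All fields
  floor at zero.
* **Transport.** Explicit diffusion with no-flux boundaries; coefficients
  above the single-pass stability bound 0.25 site²/step are integrated with
  internal substeps, because small molecules spread much faster than the
  colony grows. Antibiotic decays by mass action with the local enzyme.
* **Division.** Growth-permitted cells advance an accumulator by their
  rate (P 10% faster); on reaching 1 a cell divides into a uniformly
  chosen empty neighbour (8-neighbourhood by default). The remainder above
  1 is carried over rather than zeroed — zeroing would round every
  generation time up to a whole number of steps and erase the 10%
  advantage for most rate choices; the carry preserves mean rates exactly,
  which the advantage test exploits (11 vs 10 generations over 40 steps at
  rate 0.25). Fully enclosed cells defer with the accumulator capped at 1.

Two notions of "stagnant" coexist and both are exposed. The per-step log
flags a cell active when it is growth-permitted *and* has a free neighbour
(crowded interior cells count as stagnant, which matches how colony images
read). The state also stores the bare threshold gate, which is the model
definition of growth arrest; front-band summaries of that gate are the
right observable for depletion effects, since deep-colony crowding would
otherwise dominate the statistic.

## Default parameters

No parameter table is available in the source text, so the defaults below
are the package's own, chosen once so that the model operates in the regime
the experiments describe, and then frozen:

| parameter | default | units | role |
|---|---|---|---|
| `g_f`, `g_am`, `g_at` | 1, 0.05, 1 | conc. | growth thresholds |
| `F0` | 90 | conc. | initial food everywhere |
| `food_uptake` | 1 | conc./step | interior starves after ~`F0` steps |
| `aa_secretion`, `aa_uptake` | 0.3, 0.3 | conc./step | cross-feeding range of a few sites |
| `D_food`, `D_aa`, `D_ab`, `D_enz` | 0.2, 0.5, 0.05, 0.2 | site²/step | field transport |
| `div_rate` | 0.25 | 1/step | ~4 steps per generation |
| `p_advantage` | 1.10 | — | parasite growth advantage |
| `enz_secretion`, `ab_decay` | 0.1, 0.5 | — | cross-protection kinetics |

Under these defaults, at a 200×200 lattice: obligate colonies expand only
when both mutualists are present and keep narrow (~2-site) interleaved
sectors of constant width; supplemented amino acids (`I0 = L0 > 0`) coarsen
sectors with width-versus-radius slopes that grow with the supplement;
a mid-level supplement (0.5) roughly halves the front-band
growth-permitted fraction relative to the obligate case while expansion
speeds track that activity; the parasite is progressively excluded from the
front without antibiotic, and persists at the front — rescuing an otherwise
arrested colony — when ampicillin exceeds $g_{at}$, including only on the
lethal side of a half-plane antibiotic landscape.

# Colony statistics

All metrics act on an integer label grid (0 empty, 1..S strains) with a
centre and spacing. Sector widths are measured as arc length along a
sampled circle: nearest-site labels at an angular step of at most one site
arc, maximal runs of one non-empty label, wrap-around runs merged. The
estimator for experimental micrographs is not defined in the source
material, so only the simulation-side definition is claimed. Note that
with a cyclic strain layout an odd sector count places equal labels
adjacently, which merges them — the observable sector count is the run
count. The width-versus-radius OLS slope separates mutualistic
interleaving (splitting keeps widths constant) from drift coarsening
(widths grow).

The front edge is a per-angular-ray outermost band (default 3 sites deep),
robust to front roughness; edge composition is the strain share within it.
Colony radius is the mean over angular rays of the outermost occupied
distance, and expansion speed the trailing-half OLS slope.

Boundary sites (occupied, with a 4-neighbour of a different non-empty
strain) feed the box-counting dimension: occupied-box counts over a
geometric ladder of box sizes, with the dimension read off the log–log OLS
slope. Finite point sets corrupt the count at both ends — boxes comparable
to the whole set and boxes below the sampling scale — so the default fit
range keeps sizes with at least 8 occupied boxes and at most a quarter of
the point count; a user-supplied scaling range overrides this, and the
synthetic fixtures record the ladder aligned with their construction scales
(powers of 3 for the Koch curve), over which the estimate is unbiased.
Lattice interfaces are 2–3 sites thick, so ray-boundary checks fit above
that scale.

# Synthetic fixtures

The generator module builds every input needed for testing: exponential and
hypercycle-coculture growth curves with multiplicative lognormal noise of a
stated CV and recorded ground truth; sectored disk colonies with known
sector count, boundary angles and optional angular jitter; and rasterised
curves of known Hausdorff dimension (line, Koch curve) sampled densely
enough that every smallest-scale box along the curve is hit. Fixtures are
seeded and bit-reproducible. What passing tests on these fixtures shows is
that the estimators are correct on geometry they were designed for; the
fixtures do not emulate segmentation noise, uneven illumination, or
off-lattice cell shapes, so quantitative transfer to experimental images is
not claimed — in particular, rod-shaped-cell effects on boundary roughness
are outside this package's scope.

# Scales used in the checks

The bundled checks run at desk scale, chosen to keep the full suite in the
tens of minutes: reaction–diffusion fronts on domains of a few hundred
length units (fit windows clear of boundaries by construction), lattice
colonies at 200×200 with ~220 sweeps and 10–20 seeds per stochastic
property, and 60–160 lattices for unit-level behaviour. Stochastic claims
are tested as seeded sign tests (binomial p < 0.01) rather than as point
values.

# Known limitations

* The parasite ODE form is a minimal invention consistent with the
  two-species structure; alternatives (e.g. parasite-induced donor loss)
  are not explored.
* Pulled-front speeds converge like $1/t$, so measured Fisher speeds sit
  ~1% below $2\sqrt{\mu D}$ at the default run length; tolerances account
  for this.
* The lattice model is Eden-like with site exclusion: no cell geometry, no
  pushing, no realistic division-size law. Sector phenomenology and
  threshold logic are preserved; mechanical effects on boundary fractal
  dimension are not reproduced.
* Amino-acid supplementation interacts with the front through a finite
  supplement swept up by the advancing edge; scenarios where the
  supplement is continuously replenished (e.g. flow) are out of scope.
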