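---
title: "Modeling lymphoma growth in the lymph node: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lymphoma growth in the lymph node: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphosim)
```

## The model

`lymphosim` simulates non-Hodgkin lymphoma growing inside a murine inguinal
lymph node as a multiphase tissue mixture.  Three volume-fraction fields —
viable tumor $\rho_V$, dead tumor $\rho_D$ and host lymphocytes $\rho_H$ —
evolve on a Cartesian grid under conservation laws

$$\partial_t \rho_i + \nabla\cdot(\mathbf{u}_i\,\rho_i) = S_i,$$

with kinetic sources

$$S_V = \lambda_M\, n\, H(n - n_N)\,\rho_V - \lambda_A \rho_V
      - \lambda_N H(n_N - n)\,\rho_V,\qquad
  S_D = \textstyle\sum_i \big[\lambda_{A,i} + \lambda_{N,i} H(n_N-n)\big]\rho_i
      - \lambda_D\,\rho_D,$$

where $H$ is the Heaviside switch: cells proliferate in proportion to the
local substrate $n$ above the quiescence threshold $n_N$ and necrose below
it; apoptosis and necrosis transfer tissue into the dead compartment, which
is cleared (phagocytosed, lysed and drained as water) at rate $\lambda_D$.
Host lymphocytes do not proliferate; their homeostatic turnover is taken as
balanced (net zero) so the uninvolved tissue is stationary.

Oxygen and nutrients are lumped into one substrate $n$, normalized by its
intravascular level, and assumed quasi-steady:

$$0 = D_n \nabla^2 n + \nu\,\delta_\mathrm{vessel}\,(n_v - n)
     - (\lambda^{upt}_V \rho_V + \lambda^{upt}_H \rho_H)\, n,$$

where $\delta_\mathrm{vessel}$ marks vessel-occupied cells and delivery
saturates toward the (functional) intravascular level $n_v \le 1$, which
keeps $0 \le n \le 1$ unconditionally.  VEGF $n_V$ obeys the analogous
equation with secretion by hypoxic viable tissue ($n < n_N$) as its source
and vessels as sinks.

Bulk motion follows a generalized Darcy law,
$\mathbf{u}_i = -k_i k(x)\,(\nabla p + \gamma \nabla \mu) + \chi_n \nabla n
+ \chi_h \nabla f$ for tumor species and pressure-driven flux only for the
host, where the oncotic pressure $p$ closes the saturated mixture:
$\nabla\cdot(k\nabla p) = -S_\mathrm{total}$.  On the closed simulation box
this Poisson problem requires a zero-mean source; the compensating sink is
weighted by the host fraction, which models the physiological route of the
displaced water — drainage through the host interstitium and lymphatics.  A
uniform sink would instead siphon volume out of the tumor itself and bias
its growth rate low by the tumor-to-box volume ratio.

The healthy node is a sphere (radius 1.5 mm) centered in a 6.4 mm box; cell
mobility drops tenfold outside the sphere, delineating the node boundary.

## Parameters, units and anchors

All rates are per day internally; configuration uses the unit conventions in
`?model_parameters`.  The defaults are anchored to cellular-scale
measurements rather than chosen freely:

* **Proliferation.** A 20 h cell cycle gives $\lambda_M = 24/20 = 1.2$
  day$^{-1}$ at saturating substrate.
* **Apoptosis.** The apoptosis-to-proliferation ratio is $A =
  \lambda_A/\lambda_M = 0.4$, the value the Ki-67/Caspase-3 calibration
  yields for these lymphomas, so $\lambda_A = 0.48$ day$^{-1}$.
* **Uptake.** The hypoxia onset distance from a vessel, 80 µm (HIF-1α
  staining), is identified with the substrate screening length
  $L=\sqrt{D_n/\lambda^{upt}_V}$; with $D_n = 10^{-5}$ cm²/s this pins
  $\lambda^{upt}_V = 0.156$ s$^{-1}$ at run time (never hard-coded).  Host
  uptake defaults to half the tumor value.
* **Hypoxia threshold.** $n_N = e^{-1} \approx 0.37$: with an exponential
  perivascular profile, the threshold sits exactly one screening length from
  a vessel, which is how the 80 µm figure was measured.
* **Dead-cell clearance.** $\lambda_D = 24/5 = 4.8$ day$^{-1}$ — dead
  material resides for about the 5 h window over which the apoptotic state
  is detectable.  This value sets the steady dead fraction
  $\lambda_A/(\lambda_A+\lambda_D) \approx 9\%$, i.e. ~91% viability in
  well-fed tumor regions, consistent with H&E viability of ~87±6%.
* **Necrosis.** $\lambda_N$ is expressed in non-dimensional units (multiples
  of $\lambda_M$); baseline 6, the midpoint of the 5–7 range the
  necrosis-rate sweep procedure accepts.
* **VEGF.** Hypoxic viable tissue secretes VEGF; vessels consume it and
  the tissue clears it with a ~2 h half-life (`lambda_dec_nV` = 1e-4 /s),
  which sets a VEGF signaling range of ~0.3 mm around hypoxic regions (and
  keeps the quasi-steady VEGF solve well conditioned).
* **Vascular supply.** The homogenized delivery rate of a fully developed
  tumor vasculature is set by the CD31 calibration rule: the vascular
  support fraction $(1-f_{CD31})^{3/2}$ with the reference stained fraction
  $f_{CD31}=0.08$ gives a perfused-tissue substrate level $n_\mathrm{perf}
  = 0.88$, hence $\nu_\mathrm{ang} =
  \lambda^{upt}_V\,n_\mathrm{perf}/(1-n_\mathrm{perf})$.  The total
  angiogenic capacity equals the fully perfused node volume; a tumor that
  outgrows the node dilutes its supply as $(R_\mathrm{node}/R)^3$, which is
  what ultimately arrests growth.
* **Seed.** Lymphoma cells seed the node around Day 9; the initial lesion is
  a saturated viable ball of radius 0.45 mm at the node center — an early
  colonization occupying the perivascular core and its surroundings (~3% of
  the node volume).  The simulation clock runs from Day 9 to Day 21.

Non-dimensionalization (`nondimensionalize()`) uses the substrate screening
length (80 µm) and the mitosis time $1/\lambda_M$ — the only two scales the
data anchor numerically.

## The initial nutrient level

A quasi-steady substrate field has no memory, so a bare "initial value of
$n$" would be overwritten by the first solve.  The package reads the
initially available nutrient level `n_init` as the *functional delivery
level* of the pre-existing node vasculature: vessels initially deliver
substrate toward `n_init` and mature toward full function (level 1) at rate
`k_remodel` while hypoxia persists (VEGF exposure).  This reproduces the
observed phenomenology: the growth phase depends strongly on `n_init`
(Day-21 diameters differ several-fold between `n_init` 0.5 and 1.0), while
the terminal size does not (spread below 0.1% across `n_init` in
{0.3, 0.5, 1.0}), because every trajectory ends with a fully matured
vasculature at its capacity limit.

## Vessel models

Two representations of the tumor vasculature are provided:

* `"network"` — the discrete sprouting model: the pre-existing vasculature
  (a dense core ball, three radial stems, and a sparse parenchymal scatter
  through the node at 25% voxel density — the node is vascularized
  throughout, concentrated in the core) spawns tips where VEGF exceeds a
  threshold; tips take lattice steps with softmax weights
  $\propto \exp(\beta\,\Delta n_V)$ and no immediate backtracking, branch at
  a rate proportional to local VEGF, and anastomose (perfusing the closed
  loop) when they enter an occupied voxel.  Vessels are permanent.  All
  segments deliver substrate by default; perfusion-gated delivery is a flag.
  The per-voxel delivery coefficient applies the Dirac line-measure scaling
  $1/h$ per transverse dimension relative to the 100 µm reference voxel.
  The sprouting rates (`theta_sprout`, `p_sprout`, `branch_rate`,
  `tip_speed`) are calibrated so that the simulated Day-21 vasculature
  supports the observed phenotype — a well-perfused, minimally hypoxic
  tumor whose mean substrate approaches the CD31-derived support level —
  which the Day-21 size then follows from without further adjustment.
* `"distributed"` — the homogenized angiogenic supply described above:
  deterministic, radially symmetric, with vessel density spread over the
  tumor and capacity capped at the fully perfused node.  This is the
  configuration matched against the reduced spherical model.

## Reduced spherical model

`radial_substrate()`/`radius_rhs()`/`terminal_diameter()` implement the 1D
reduction: a quasi-steady radial substrate solve feeding the uniform-density
mass balance

$$\frac{dR}{dt} = \frac{1}{R^2}\int_0^R
  \big[\lambda_M n H(n-n_N) - \lambda_A - \lambda_N H(n_N-n)\big]\,r^2\,dr .$$

Growth is exponential while the tumor is within its supply capacity and
arrests when the capacity-diluted interior substrate falls to the level
where proliferation balances death — at baseline essentially where
$\langle n \rangle \to A$, which is why the terminal size is governed by the
apoptosis-to-proliferation ratio.  At $A = 0.4$ the terminal diameter is
about 5.8 mm, monotone decreasing in $A$; at $A \gtrsim 0.9$ the seed never
grows.  Radius integration uses fixed-step classical Runge–Kutta
(`deSolve`, step 0.02 day, radial mesh 10 µm); the plateau is declared when
the radius moves less than 2 µm over a day, and growth beyond 5 mm radius is
reported as unbounded.

## Numerics

* **Elliptic solves** (substrate, VEGF, pressure): matrix-free
  Jacobi-preconditioned conjugate gradients in compiled code, harmonic-mean
  face conductances (flux continuity across the tenfold node-boundary
  mobility jump), relative residual $10^{-8}$, warm-started from the
  previous step.  The pure-Neumann pressure problem is deflated (zero-mean
  gauge).
* **Transport**: conservative donor-cell upwind by default — positivity
  over accuracy; an optional minmod-limited MUSCL reconstruction roughly
  halves interface smearing and is used where interface sharpness matters
  (solver cross-checks).  Time stepping is first-order operator splitting
  with explicit kinetics, dt capped at 0.01 day and adapted under the
  advective CFL bound (0.45).
* **Pressure solve**: the pure-Neumann Poisson problem is the stiffest
  solve in the loop and uses a geometric multigrid V-cycle (cell-centered
  linear transfers, damped-Jacobi smoothing) as the CG preconditioner,
  verified against the plain Jacobi-CG route to 4e-10.
* **Quasi-steady refresh**: substrate, VEGF, pressure and velocities are
  re-solved every 5 transport steps (0.05 day at the dt cap) by default;
  they equilibrate instantaneously relative to tissue motion, so this
  splitting error is far below the advective error.  The solver
  cross-check refreshes every step.
* **Heaviside switches** are exact ($H(0)=0$); a smoothed variant of width
  `eps_H` in $n$ exists for stiffness experiments and is off by default.
* **Saturation**: fractions are clipped to $[0,1]$ and the solid sum to 1;
  clipped mass is recorded per step.  Discrete mass bookkeeping (transport
  conservative to round-off; mass change = integrated sources) is tested to
  $10^{-8}$.
* **Adhesion**: the double-well interface energy and its variational
  derivative are implemented (and verified to decrease the 1D interface
  energy — note the flux must run *down* the chemical-potential gradient),
  but $\gamma = 0$ at baseline: in a saturated three-species mixture a
  tumor-only adhesion flux must be balanced by an explicit counter-flux in
  the other species, and without that full multi-species treatment the term
  merely feeds the saturation clipping.  Chemotaxis and haptotaxis
  coefficients default to 0 (the ECM field is uniform and static at
  baseline, so haptotaxis would be inert regardless).

### Problem sizes

The packaged runs use desk-scale grids chosen for resolution adequacy: the
baseline Day-21 simulation runs 3D on $32^3$ cells (200 µm spacing, the
6.4 mm box); the solver cross-check against the reduced model runs at
$64^3$ (100 µm, the reference spacing); the reduced model integrates a
10 µm radial mesh.  The 1D slab tests resolve the 80 µm screening length at
$L/8$ and verify second-order convergence.

## What the solver cross-check does and does not show

On a spherically symmetric configuration (distributed supply, MUSCL,
dt 0.02 — well inside that run's CFL bound), the 3D solver's radius
trajectory tracks the reduced model within 5% over days 9–21 when both
share their idealizations — fast dead-cell clearance and no necrosis
(measured: 4.8% peak deviation at $64^3$).  With necrosis on, the finite-width numerical interface (1–2
cells even with MUSCL) straddles the threshold $n_N$ and is continuously
eroded, a resolution artifact that decays under refinement (−17% at $32^3$
upwind → −4.4% at $64^3$ MUSCL in the matched limit) but does not vanish at
desk scale.  The same mechanism, plus the volume occupied by dead tissue
until cleared, is why the full 3D baseline reaches ~5 mm at Day 21 while
the idealized reduced theory plateaus near 5.8 mm — the simulation sits
below its own theory by design, not by accident.

## Synthetic IHC fixtures

`synth_ihc()` generates five-section stain-count tables (Ki-67, Caspase-3,
CD31, HIF-1α, H&E; core and periphery per section; binomial counts around
preset fractions, a pole-ward blend in S1/S5).  The baseline preset encodes
the phenotype the model is built around: Ki-67 ≈ 85% (nearly all cells
cycling), Caspase-3 ≈ 10% (λ_A ≈ 0.48/day, A ≈ 0.4), CD31 ≈ 8% with central
enrichment, minimal HIF-1α (2% core / 10% periphery), H&E viability ~90%.
The `"resistant"` preset adds the 4-fold central endothelial enrichment and
center-dense viability; `"sensitive"` the periphery-dense variant.  These
are synthetic stand-ins for slide-derived counts: they reproduce the
marginal stained fractions and core/periphery contrasts, but none of the
spatial correlation, sectioning artifacts or inter-animal variability of
real slides, so passing calibration tests demonstrates correctness of the
conversion pipeline, not fidelity to any particular animal.

The necrosis-rate sweep (`necrosis_sweep()`) runs the reduced model to its
plateau at `n_init = 0.5` across a grid of non-dimensional necrosis rates,
records the hypoxic fraction and average apoptosis rate, and accepts the
contiguous set of rates whose outputs fall inside acceptance bands; accepted
rates are re-checked across an `n_init` grid.  The shipped bands derive from
the synthetic fixture presets (they are not measured ranges) — with them the
sweep accepts a contiguous low-to-mid interval of necrosis rates whose width
illustrates the procedure's tolerance; measured hypoxic-fraction and
apoptosis-rate ranges would be supplied by the user in any real calibration.

## Virtual histology

`extract_sections()` emulates the experimental scheme: five planes spanning
the tumor extent (S1/S5 at the poles, S3 central), per-plane area-fraction
statistics restricted to the tumor region, split into a core and a
periphery defined as the 200 µm shell inside the tumor boundary (the 0.5
level set of total tumor fraction, eroded by the shell width).  The
proliferating and apoptotic "stains" are the calibration formulas inverted
(rate × detectability window), so virtual IHC and rate calibration are
mutually consistent by construction.  Real sections sample fixed 100 µm
spacing; equal spanning spacing is used instead so five sections always
cover the tumor.

## Known limitations

* The node boundary is a mobility contrast, not an elastic membrane; node
  deformation mechanics are out of scope.
* Vessels never regress, carry no blood-flow computation, and deliver
  uniformly; perfusion gating is a flag, not a flow model.
* The advective interface is 1–2 cells wide; quantities that live in an
  80 µm boundary layer (rim necrosis, rim hypoxia) are under-resolved on the
  200 µm production grid and should be read as first-order estimates.
* Drug transport and response are not modeled.
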