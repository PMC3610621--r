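# lymphosim

Continuum mixture simulation of non-Hodgkin lymphoma growth in a murine
inguinal lymph node, with the immunohistochemistry-based calibration that
turns stain counts into model rates.

## The problem and the model

Aggressive B-cell lymphoma seeds the inguinal lymph node around Day 9 after
engraftment and grows to a 4–6 mm tumor by Day 21.  Whether and when that
growth arrests is governed by transport: oxygen and nutrients reach tissue
only within ~80 µm of a vessel, so the tumor's size is a balance between
proliferation, death and the vasculature's capacity to keep pace.

`lymphosim` models the node contents as a saturated multiphase mixture.
Viable tumor, dead tumor and host volume fractions ρ_i obey

    ∂ρ_i/∂t + ∇·(u_i ρ_i) = S_i

with proliferation λ_M·n·H(n − n_N) above the substrate threshold n_N,
apoptosis λ_A, necrosis λ_N below the threshold (both transferring tissue
to the dead compartment) and dead-cell clearance λ_D.  The substrate n and
VEGF n_V obey quasi-steady reaction–diffusion sourced by a vessel network;
bulk motion follows a generalized Darcy law driven by the oncotic pressure
that proliferation generates, with cell mobility reduced tenfold outside
the node sphere.  Angiogenesis is a discrete sprouting lattice model: tips
initiate on perfused vessels where VEGF is high, migrate up the VEGF
gradient (softmax-biased random walk), branch, and anastomose.

Cellular-scale calibration converts IHC stain counts into rates:

    λ_M·⟨n⟩ = (Ki-67 fraction / 20 h) · 24 h/day
    λ_A     = (Caspase-3 fraction / 5 h) · 24 h/day
    vascular support = (1 − CD31 fraction)^{3/2}   (supplies ⟨n⟩)
    hypoxic fraction = (HIF-1α fraction)^{3/2}

For these lymphomas the calibration gives A = λ_A/λ_M ≈ 0.4, and a
radially symmetric reduced model (quasi-steady radial substrate solve
feeding a radius ODE) predicts the terminal size from A alone.

## Worked example

```r
library(lymphosim)

# calibrate rates from a (synthetic) IHC stain-count table
tab <- synth_ihc(rng_seed = 1)
calibrate_ihc(tab)
#> IHC calibration result
#>   lambda_M = 1.095 /day  (<n> = 0.912)
#>   lambda_A = 0.519 /day   A = lambda_A/lambda_M = 0.474
#>   vascular support 0.912, hypoxic cell fraction 0.0217

# terminal size of the reduced spherical model at the calibrated A ~ 0.4
terminal_diameter(0.4)
#> [1] 5.809946        # mm, plateau reached at day 25

# Day-9 -> Day-21 simulation in 3D (32^3 cells, 200 um), sprouting network
p   <- model_parameters()
run <- run_simulation(p, make_grid(6.4, 200, dim = 3), rng_seed = 1)
tail(run$trajectory[, c("time", "diameter_mm", "hypoxic_fraction")], 1)
#>    time diameter_mm hypoxic_fraction
#> 49   21        5.36           0.0236

# virtual histology of the final state
head(extract_sections(run$state, p), 2)
```

The calibration output says: ~85% of cells are inside the 20 h cycle
(λ_M ≈ 1.1–1.2/day once corrected by the vessel-derived mean substrate),
~10% are in the 5 h apoptotic window (λ_A ≈ 0.5/day), so death runs at
~40% of the proliferation rate.  With that ratio the reduced model
plateaus near 5.8 mm, and the full simulation — which also carries dead
tissue until it is cleared — reaches 5.2–5.4 mm by Day 21, inside the
measured 4–6 mm range.

A command-line interface wraps the same functions:

```sh
inst/cli/lymphosim simulate --config run.cfg --seed 1 --out results/
inst/cli/lymphosim reduce --A 0.4 --out results/
inst/cli/lymphosim calibrate --ihc counts.csv
```

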