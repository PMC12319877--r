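# rtefield

Real-time computation of the TMS-induced electric field in the brain by
mode expansion, reciprocity and Huygens surface equivalence.

## What this solves, and for whom

Transcranial magnetic stimulation (TMS) induces an electric field in the
cortex that depends sensitively on where the coil is held. Navigated TMS,
coil-placement optimization and closed-loop dosing all need that field
*per coil pose, while the coil moves* — far faster than a conventional
finite-element (FEM) solve. This package is for researchers in brain
stimulation dosimetry and neuronavigation methods who want a compact,
fully testable implementation of a two-stage real-time solver:

- **Offline (once per head + coil):** probe the head model with `N_m`
  realizations of Gaussian white-noise magnetic surface currents on a
  closed Huygens surface 1 mm outside the scalp; solve the quasi-static
  scalar-potential FEM problem per realization; compress the brain fields
  with a volume-weighted QR+SVD into orthonormal modes `M_i`; re-impress
  each mode as a current source and store its equivalent electric and
  magnetic surface currents `J_S,i`, `K_S,i` on the Huygens surface;
  pre-sample the coil's primary fields on a Cartesian grid.
- **Online (per placement, milliseconds of arithmetic):** move the Huygens
  facet centers into the coil frame by `T^-1`, trilinearly interpolate the
  primary fields `E_p`, `H_p`, evaluate the reciprocity quadrature

  `a_i = sum_j A_j [ E_p(r_j) . J_S,i(r_j) - H_p(r_j) . K_S,i(r_j) ]`,

  and reconstruct `E(r) = dI/dt * sum_{i<=N} a_i M_i(r)` at the
  middle-grey-matter evaluation surface.

Everything needed to exercise the pipeline from scratch is built in: a
five-shell concentric-sphere head phantom (WM/GM/CSF/skull/scalp at 0.126,
0.275, 1.654, 0.01, 0.465 S/m), a printed-geometry figure-8 coil builder
(two counter-wound 9-turn windings, 53/88 mm diameters), a direct
first-order FEM reference solver, and the global/local error metrics
(GVE, GME, LVE, LME) used to validate the expansion.

## Worked example

```r
library(rtefield)

# five-shell sphere phantom (coarse), figure-8 coil, 60-mode session
ph   <- make_layered_sphere_phantom(target_edge = 8)
coil <- build_figure8_coil()
ses  <- tms_precompute(ph$mesh, coil, ph$mid_gm, n_modes = 60, seed = 1,
                       scalp = ph$scalp, verbose = FALSE)
ses

# a coil placement tangent to the scalp, 5 mm standoff, and its field
T <- sample_scalp_placements(ph$scalp, 1, seed = 2)[[1]]
E <- predict(ses, T)
cat(sprintf("peak |E| = %.1f V/m at dI/dt = %.2g A/s\n",
            max(sqrt(rowSums(E^2))), ses$dIdt))

# how good is the expansion here? compare with the direct FEM reference
Eref <- reference_solve(ses, ph$mesh, T)
g <- global_errors(E, Eref)
cat(sprintf("GVE %.1f%%  GME %.1f%% vs direct FEM\n", g$gve, g$gme))
```

```
Real-time TMS E-field session
  modes: 60 (singular values 0.00907 .. 0.0028)
  head: 5120 tets (2240 ROI); Huygens: 320 facets at 1 mm
  coil: 'figure8-53/88mm'; grid 48 x 48 x 50 at 4 mm
  evaluation surface: 320 facets; dIdt = 6.6e+07 A/s
peak |E| = 73.9 V/m at dI/dt = 6.6e+07 A/s
GVE 63.8%  GME 45.3% vs direct FEM
```

The session `print` method summarizes what was precomputed. `peak |E|` is
the maximum field magnitude over the middle-grey-matter barycenters at the
stated coil current slew rate — tens of volts per meter is the physiological
TMS range. GVE and GME are the global vector and magnitude errors (percent,
2-norm over all evaluation points) of the 60-mode expansion against a
from-scratch first-order FEM solve of the same placement; on this coarse
phantom a 60-mode expansion tracks the reference only roughly, and the
convergence with mode count is mapped systematically by
`convergence_study()` and the acceptance script below.

A command-line front end for the same pipeline (phantom generation,
precompute, per-placement solves, validation reports) is installed at
`inst/scripts/tms-rt`.

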