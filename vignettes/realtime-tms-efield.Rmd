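---
title: "Real-time TMS E-field computation: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time TMS E-field computation: model, numerics and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Transcranial magnetic stimulation (TMS) drives a strong, rapidly changing
current through a coil held over the scalp; the changing magnetic field
induces an electric field in the cortex. Navigated TMS and closed-loop
dosing need that E-field *while the operator moves the coil*, which rules
out running a finite-element solve (seconds to minutes) per coil pose.

`rtefield` implements a two-stage answer. A slow **offline stage**, run once
per head model and coil, compresses everything the head does to any
external source into a small orthonormal basis of brain E-field *modes*
plus, for each mode, a pair of fictitious *equivalent surface currents* on
a closed Huygens surface just outside the scalp. The **online stage** then
prices any rigid coil placement with two dense matrix products and a
trilinear interpolation: milliseconds of arithmetic, no mesh, no solver.

## Model and assumptions

The field is quasi-static: with a separable coil current
$J(\mathbf r,t) = I(t)\,J(\mathbf r)$ and $I'(t)$ normalized to unit peak,
the brain E-field is $\mathbf E(\mathbf r,t) = I'(t)\,\mathbf E(\mathbf r)$
and the spatial part is expanded as

$$\mathbf E^{(N_m)}(\mathbf r) \;=\; \sum_{i=1}^{N_m} a_i\,
\mathbf M_i(\mathbf r), \qquad \mathbf r \in \Omega,$$

where $\Omega$ is the brain (white + grey matter) and the modes
$\mathbf M_i$ are orthonormal under the volume inner product
$\langle f, g\rangle = \int_\Omega f \cdot g\, d\mathbf r$. Conductivity is
piece-wise constant per tetrahedron, the exterior is insulating, and the
scalar potential solves the pure-Neumann Poisson problem
$\nabla\!\cdot\sigma\nabla\varphi = \nabla\!\cdot\sigma\mathbf E_p$ with
$\hat{\mathbf n}\cdot\sigma\nabla\varphi =
\hat{\mathbf n}\cdot\sigma\mathbf E_p$ on the scalp. Fields are represented
per-tetrahedron (P1 elements, constant gradients).

**Offline stage.** The basis is built by probing: $N_m$ realizations of
Gaussian white-noise *magnetic* surface current densities are placed on the
Huygens surface (magnetic currents need not be divergence-free, so i.i.d.
normal 3-vectors per facet are admissible); each realization's primary
field is summed by single-point quadrature and corrected by an FEM solve;
the resulting brain fields are stacked into a matrix $Z$ whose column $i$
holds the field components scaled by $\sqrt{V_k}$ (element volume), so
Euclidean dot products of columns equal the volume inner product of fields.
An economic QR ($Z = QR$) followed by an SVD of $R$ gives
$U = Q\tilde U$; mode $i$ is column $i$ of $U$ with the $\sqrt{V_k}$
weight divided out, ordered by singular value. Truncations of one
max-rank basis are nested, so one 450-mode session serves every smaller
mode count.

Each mode is then re-impressed as a *source*: the conduction response
$-\sigma\nabla\varphi$ is solved per mode, and the total current
$\mathbf J = \mathbf M_i - \sigma\nabla\varphi$ is radiated to the Huygens
surface. On that surface the (inductive) electric field is
$-\frac{\mu_0}{4\pi}\int \mathbf J / \lVert\mathbf r-\mathbf r'\rVert$
and the magnetic field is the Biot–Savart integral; the equivalence
boundary conditions give the surface currents
$\mathbf J_S = \hat{\mathbf n}\times\mathbf H$ and
$\mathbf K_S = -\hat{\mathbf n}\times\mathbf E$.

**Online stage.** By electromagnetic reciprocity applied twice (once
between the mode current and the coil, once between the equivalent surface
currents and the coil in free space), the expansion coefficients need only
the coil *primary* fields on the Huygens surface:

$$a_i \;=\; \sum_{j=1}^{N_d} A_j\left[\mathbf E_p(\mathbf r_j)\cdot
\mathbf J_{S,i}(\mathbf r_j) - \mathbf H_p(\mathbf r_j)\cdot
\mathbf K_{S,i}(\mathbf r_j)\right],$$

with one quadrature point per facet. For a placement $T$ the facet centers
are moved into the coil frame by $T^{-1}$, the primary fields are
trilinearly interpolated from a precomputed Cartesian grid, rotated back to
the head frame, and contracted against the stored operator; the field at
the evaluation surface is the weighted mode sum scaled by $dI/dt$.

Two sign conventions deserve a note. The inductive field on the surface
carries a minus sign ($\mathbf E = -\partial_t \mathbf A$); dropping the
scalar-potential part outside the head is exact at quasi-static order for
coefficients because closed-loop coil currents integrate any gradient field
to zero. Both signs (and every constant) are pinned end-to-end by the
package's reciprocity oracle: coefficients from the surface integral must
match the direct projection $\langle \mathbf M_i, \mathbf E\rangle$ of a
reference FEM solve.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_modes` | 400–450 | realizations drawn = maximum expansion rank |
| `huygens_distance` | 1 mm | offset of the Huygens surface from the scalp |
| `grid_spacing` | 4 mm | primary-field grid step in the coil frame |
| `standoff` | 5 mm | coil-center height used for placements and the grid envelope |
| `dIdt` | 6.6e7 A/s | peak coil current derivative (applied at reconstruction) |
| conductivities | 0.126 / 0.275 / 1.654 / 0.01 / 0.465 S/m | WM, GM, CSF, skull, scalp |
| `tol` | 1e-10 | relative residual of the FEM solves |

Geometry is in mm at every interface (file formats, mesh objects); all
physics is computed in SI meters internally, so fields are in V/m.

## The synthetic phantom

`make_layered_sphere_phantom()` builds five concentric spherical shells
(default interface radii 70/75/78/82/85 mm) as nested subdivided
icosahedra joined by consistently split prisms, with a central tetrahedral
fan. The subdivision level is `floor(log2(r_max / (2 * target_edge)))` and
the innermost ball is cut radially in steps of about `6 * target_edge`; at
the default `target_edge = 4` this gives 24,320 tetrahedra and 4,495 nodes
— deliberately desk-scale. The "middle grey matter" evaluation sphere sits
at the mid-radius of the second shell (72.5 mm).

What the phantom emulates: conformal tissue layers with realistic
conductivity jumps (notably the resistive skull), a closed scalp for the
Huygens construction, and spherical symmetry that supplies two free
physics oracles — a uniform conservative field must induce nothing in a
homogeneous conductor, and the interior field must not depend on the
radial conductivity profile. What it does not emulate: cortical folding
(which dominates where real E-field hotspots form), tissue anisotropy, and
realistic mesh grading. Passing tests on the phantom therefore validate
the *machinery* (operators, signs, quadratures, transforms), not clinical
field accuracy on a head.

A consequence worth stating plainly: at this element budget the sphere's
1st-order FEM reference itself carries a double-digit percentage
discretization error (the surface edge length is ~9 mm), and the
mode expansion — like the method it implements — converges quickly only to
the smooth part of the solution and decelerates near the solver's error
floor. The mode-count convergence curves produced by
`convergence_study()` on the phantom are therefore expected to flatten at
a much higher level than the few-percent figures achievable on
million-element head meshes; `scripts/acceptance.R` computes and reports
the exact values for the default conditions rather than asserting hoped-for
ones.

## Numerical choices

- **Pure-Neumann solves.** The right-hand side is projected onto the
  operator's range (zero mean), the system is solved by a sparse Cholesky
  factorization of the one-node-grounded operator — computed once and
  shared across all ~2·`n_modes` right-hand sides — and the potential is
  gauge-fixed to zero mean. For a compatible right-hand side the grounded
  solve is an exact particular solution, so no Dirichlet-pinning error
  concentration arises; a Jacobi-preconditioned CG path (`method = "cg"`)
  is available and agrees to solver tolerance. Residuals are verified
  against `tol` and solves are deterministic.
- **Quadratures.** All radiation integrals use a single point per source
  element (facet center / tet centroid) and direct chunked summation in
  double precision; no fast-multipole acceleration at desk scale. The
  accuracy-controlling parameter is the gap between the Huygens surface
  and the nearest tetrahedron centroids relative to the element size.
- **RNG.** Noise realizations use per-realization sub-seeds drawn from a
  sequential master stream, so realization *i* is bit-reproducible from
  `(seed, i)` and independent of how many realizations are requested; the
  caller's RNG state is restored.
- **Degenerate inputs.** Zero-area facets, zero-volume tets, unknown
  tissue tags, non-manifold boundaries, incompatible right-hand sides,
  rank-deficient realization sets (relative singular value below 1e-12)
  and evaluation points outside the ROI are all hard errors or explicit
  warnings; out-of-grid interpolation is an error, never extrapolation.
- **Point location** uses a uniform-grid spatial hash over tet bounding
  boxes with a barycentric containment test (tolerance 1e-9); ties on
  shared faces resolve to the first candidate, which is immaterial for
  piece-wise constant sampling.

## Design decisions on open questions

- *Node normals for the 1 mm extrusion*: angle-weighted averages of
  incident facet normals — robust to irregular valence and exactly radial
  on the sphere.
- *$\sqrt{V_k}$ versus $V_k$ weighting*: only the square-root weighting
  makes column dot products equal the volume inner product and the mode
  Gram matrix the identity; the package enforces this with a Gram test at
  1e-8.
- *Figure-8 winding law*: two side-by-side sets of nine concentric closed
  circular loops (radii linearly spaced between the printed 26.5 and 44 mm),
  mirror-imaged so the windings are counter-wound. A spiral
  interpolation was considered and rejected: closing the spiral polygon
  requires a radial return chord whose field breaks the coil's half-turn
  symmetry by several percent near the scalp, while concentric circles
  close each turn exactly and keep the symmetry to machine precision.
- *Realizations per mode count*: one max-rank run (realizations = largest
  requested mode count); smaller counts are nested truncations.
- *Error norms*: unweighted 2-norms over evaluation samples; an
  area-weighted variant exists (`weights=` in `global_errors()`) but is
  not the default.

## Problem sizes used in the shipped validation

Unit tests run on a coarse phantom (subdivision 2; 5,120 tets, 320 scalp
facets) with 8–60 modes. The acceptance suite and `scripts/acceptance.R`
use the default phantom (24,320 tets), a 450-mode session, and 100 seeded
tangential placements at 5 mm standoff, comparing the online solver
against the direct FEM reference at the 1,280 middle-grey-matter
barycenters — the package's chosen desk-scale study conditions.

## Known limitations

- 1st-order elements only; no anisotropic conductivity; no adaptive
  meshing. The reference solution shares every one of these limitations,
  which is precisely what the error metrics are defined against.
- Direct summation makes the offline stage O(N_tets × N_facets) per batch;
  this is minutes at phantom scale and would need acceleration for
  million-element heads.
- The online stage is plain R linear algebra: fast enough for interactive
  use at phantom scale, but a millisecond-latency loop on million-element
  cortical meshes would require GPU-resident matrices.
- Sessions serialize with `saveRDS()`; they are R-native containers, not
  interchange files.
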