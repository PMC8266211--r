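---
title: "Comparing constitutive laws and fiber architectures for aortic valve leaflets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing constitutive laws and fiber architectures for aortic valve leaflets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvemech)
```

## The modelling problem

Simulations of aortic valve (AV) dynamics need two structural modelling
choices before any fluid–structure computation can start: a constitutive
law for the leaflet tissue and a collagen fiber architecture on the
leaflet surface. `valvemech` implements the desk-scale computational chain
used to compare such choices: calibration of candidate hyperelastic laws
to planar biaxial test data, rule-based fiber field construction, a
lumped afterload model, transvalvular hemodynamic indices, and a
multi-criteria normalization scheme that ranks the candidate
law/architecture combinations. The expensive 3D immersed-boundary
fluid–structure solver itself is deliberately out of scope: its waveform
and field outputs enter this package as data.

## Constitutive laws

Leaflet tissue is modelled as incompressible, anisotropic and
hyperelastic, with one preferred (collagen) direction $f_0$. With
$C = F^TF$, $I_1 = \mathrm{tr}\,C$ and $I_4 = f_0\cdot(Cf_0)$, the three
candidate strain-energy densities are

$$W_1 = C_{10}\left(e^{C_{01}(I_1-3)}-1\right)
      + \frac{k_1}{2k_2}\left[e^{k_2(I_4-1)^2}-1\right],$$

$$W_2 = \mu(I_1-3) + c_0\left[e^{c_1(I_1-3)^2 + c_2(I_4-1)^4}-1\right],$$

$$W_3 = C_1(I_1-3) + \frac{a}{2b}\left[e^{b(I_4-1)^2}-1\right].$$

W1 is exponential in both the matrix and the fiber response, W2 couples
both invariants inside one exponential, and W3 keeps a linear
(neo-Hookean) cross-fiber response. Stress-like parameters
($C_{10}, k_1, \mu, c_0, C_1, a$) carry kPa; the exponents are
dimensionless; all parameters are constrained non-negative, which is also
the lower bound used during calibration. The Cauchy stress of each law has
the common structure

$$\sigma = -p\,I + 2W_{,I_1}\,B + 2W_{,I_4}\, f\otimes f,
\qquad f = Ff_0,$$

with $B = FF^T$ and the Lagrange multiplier $p$ enforcing
incompressibility. `cauchy_stress()` evaluates this directly, and the test
suite checks it against central finite differences of `strain_energy()` —
an oracle that is independent of the analytic coefficient derivation.

Two post-processing scalars follow the conventions of valve mechanics:
the fiber strain $f_0\cdot(E f_0) = (I_4-1)/2$ and the fiber stress
$\hat f\cdot(\sigma\hat f)$. For the fiber stress we normalize the
deformed direction $\hat f = Ff_0/|Ff_0|$, so the value is a true normal
(traction) component; the unnormalized form would scale it by $I_4$. This
was a genuinely open convention choice — reported regional stresses do not
disambiguate it — and the normalized form was chosen for its physical
interpretation.

### Plane-stress biaxial response

A planar biaxial test stretches a square leaflet sample along the fiber
(circumferential, $\lambda_1$) and cross-fiber (radial, $\lambda_2$) axes.
With exact incompressibility, $\lambda_3 = 1/(\lambda_1\lambda_2)$, and
the plane-stress condition $\sigma_{33}=0$ eliminates $p$ analytically:
$p = 2W_{,I_1}\lambda_3^2$, giving closed-form $\sigma_{11}, \sigma_{22}$.
A shear-free diagonal deformation is assumed throughout, which matches
stress-controlled protocols with markers aligned to the material axes.
The analytic elimination is verified against a bisection root-finder on
$p$ to $10^{-10}$ kPa.

```{r biaxial-curve}
p1 <- porcine_leaflet_params("W1")
planar_biaxial_stress(p1, c(1, 1.05, 1.1), c(1, 1.03, 1.05))
```

## Calibration to biaxial data

`fit_biaxial()` minimizes the summed squared stress residuals of both
directions (the standard unweighted least-squares loss for this kind of
data) subject to non-negativity, using L-BFGS-B. The exponential laws
have narrow curved valleys and genuine local minima, so the optimizer is
multi-started: two deterministic starts at magnitudes typical of
soft-tissue exponential laws, plus seeded log-uniform random restarts in
$[10^{-2}, 10^3]$, followed by a Nelder–Mead polish and a final bounded
refinement. Exponent overflow is guarded by capping exponent arguments;
non-finite losses map to a large finite penalty.

Goodness of fit is reported per sample as $R^2 = 1 - SSE/SST$ with $SST$
the total sum of squares of the *pooled* experimental stresses (both
directions about one mean), so each sample has a single $R^2$; and as an
average error in kPa defined as the per-sample RMSE
$\sqrt{SSE/(2n)}$, aggregated across samples as mean ± SD by
`aggregate_fits()`. Both definitions were open choices: published tables
report a single "average error (kPa)" per law without defining it, and
the RMSE convention reproduces the printed magnitudes.

The bundled averaged parameter sets (`porcine_leaflet_params()`) are the
published values calibrated to nine porcine leaflet samples; the raw
experimental data are not public, so these constants act as ground truth
for synthetic-data recovery studies, not as fitting targets.

## Synthetic biaxial data

`generate_biaxial()` emulates the stress-controlled protocol used for
leaflet characterization: equibiaxial 1:1 stress ratio, loaded to a peak
stress chosen by Laplace's law for a thin spherical shell,
$\sigma = Pr/2h \approx 400$ kPa for a 2 cm radius of curvature, 120 mmHg
transvalvular pressure and 0.04 cm thickness. At each target stress the
stretches solve $\sigma_{11}=\sigma_{22}=s$ by a damped 2×2 Newton
iteration with continuation across load levels. Measurement error is
multiplicative Gaussian noise on the stresses with configurable
coefficient of variation (2 % in the recovery studies).

What this generator does *not* emulate: preconditioning hysteresis
(samples are assumed to start from a settled zero-load reference), shear
from marker misalignment, inter-sample biological variability beyond the
noise model, and rate effects. Parameter-recovery results on these data
therefore show the identifiability of the laws under the protocol, not
the full variability of wet-lab data.

```{r recovery}
d <- generate_biaxial(porcine_leaflet_params("W3"),
                      biaxial_protocol(n_points = 15))
fit_biaxial("W3", d, restarts = 2, seed = 1)
```

## Rule-based fiber architectures

Two collagen architectures are built on a triangulated leaflet surface by
solving a surface Laplace problem and normalizing its gradient,
$f = \nabla u / |\nabla u|$:

* **FD1 (body-fitted)**: point Dirichlet constraints $u = 1$ and $u = 0$
  at the two commissure corner vertices, natural conditions elsewhere.
  Point constraints are borderline in the continuum but well-posed
  discretely; this literal construction is used because it is what the
  architecture definition states.
* **FD2 (circumferential)**: $u = 0$ and $u = 1$ on the two attachment
  edge sets, natural conditions on the free edge.

The discretization is the standard piecewise-linear cotangent Laplacian
(`cotan_laplacian()`), assembled per triangle with zero row sums and
symmetric structure; degenerate triangles abort assembly with the
offending index. Dirichlet constraints are imposed by row reduction and
the reduced system is solved with a sparse direct factorization
(`Matrix`). The fiber field lives per triangle — the gradient of a linear
element is element-wise constant — and each vector is unit length and
tangent to its triangle. Triangles whose gradient magnitude falls below
$10^{-12}\,\mathrm{range}(u)/\mathrm{diameter}$ (FD1 has an interior
saddle where $\nabla u$ can vanish) inherit the area-weighted average
direction of their edge neighbors, projected back to the triangle plane;
isolated degenerate triangles are flagged with a zero vector and a
warning.

Verification uses analytic harmonics: on a flat square, FD2 yields
$u = x$ to solver precision with uniform fibers; on a structured annular
sector the angular harmonic $\theta/\Delta\theta$ is reproduced exactly
(a symmetry property of the structured mesh), while the radial
log-harmonic — not exactly representable — converges at second order in
the mesh size. The discrete maximum principle $0 \le u \le 1$ is asserted
on every fixture.

`generate_leaflet_mesh()` provides a labelled idealized semi-lunar
leaflet: a U-shaped attachment arc on a cylinder of the aortic tube
radius (1.3 cm), a free edge bowing toward the axis for coaptation, with
commissure corners, attachment halves and free edge labelled for both
architectures.

## Windkessel afterload

The three-element Windkessel converts transvalvular flow into aortic
pressure: characteristic resistance $R_c$ in series with peripheral
resistance $R_p$ parallel to compliance $C$,

$$C\frac{dP_{Wk}}{dt} + \frac{P_{Wk}}{R_p} = Q, \qquad
  P_{Ao} = QR_c + P_{Wk}.$$

Defaults are the human "Type A" beat values $R_c = 0.033$,
$R_p = 0.79$ mmHg s/mL, $C = 1.75$ mL/mmHg, $P_{Wk}(0) = 85$ mmHg. The
ODE is advanced by the exact exponential update for a constant-in-step
flow, which is unconditionally stable and exact up to flow sampling — no
step-size restriction is inherited from any outer solver.
`wk_simulate()` offers two per-interval flow conventions: the trapezoid
average (default; second-order for smooth flows and verified against an
adaptive ODE reference) and left-hold (exact for piecewise-constant
flows). Flow out of the valve into the aorta is positive.

## Hemodynamic indices

From a cycle waveform with event times (begin/end systole $t_{bs},
t_{es}$, full closure $t_{close}$, cycle end), `hemodynamic_indices()`
computes:

* **Regurgitant fraction** $RF = (V_R + V_L)/V_F \times 100\,\%$, with
  the forward, closing-regurgitation and leakage volumes integrated from
  the clipped flow over their phases;
* **Mean transvalvular pressure gradient**, the systolic time average of
  the near-valve pressure difference;
* **Effective orifice area**
  $EOA = Q_{rms}/(51.6\sqrt{\Delta P/\rho})$ in cm² with $Q$ in mL/s,
  $\Delta P$ in mmHg (defaulting to the mean systolic gradient) and
  $\rho = 1$ g/mL;
* **Energy loss** $E_L = 0.1333\int \Delta p\, Q\,dt$ over the cycle in
  mJ, $\Delta p = P_{Ao} - P_{LV}$. The signed integral is negative in
  every phase (the valve dissipates ventricular work); the magnitude is
  reported by default, matching how the index is conventionally printed.
  The 0.1333 factor is the SI value of 1 mmHg·mL in mJ to four
  significant figures.

All quadrature is trapezoidal with linear interpolation at window
endpoints: second order and agnostic to non-uniform grids. Event times
are explicit inputs because published state definitions (pre-open, fully
opened, pre-close) are rarely quantified; `detect_events()` offers a
threshold detector (crossings of 1 % of peak flow; closure when the flow
settles within the threshold for 10 ms) for waveforms lacking annotations.

## The surrogate cycle generator

Real transvalvular waveforms come from 3D FSI simulation or measurement.
For testing, `generate_waveform()` runs a deliberately simple
phenomenological surrogate: a smooth analytic LV pressure pulse (0.8 s
cycle), a prescribed valve opening function scaling a quasi-static
orifice law $Q = 51.6\,A(t)\sqrt{|\Delta P|}$ solved implicitly against
the Windkessel afterload, and a small leak conductance after closure.
Its defaults were chosen once, on physiological grounds, so the
resulting cycle lands inside the bands spanned by published valve FSI
studies: forward volume 75–95 mL, RF 4–19 %, mean gradient 2–10 mmHg,
EOA 2.8–4.3 cm², energy loss 80–210 mJ. The defaults give
$V_F \approx 83$ mL, $RF \approx 9\,\%$, $TPG \approx 5.3$ mmHg,
$EOA \approx 3.3$ cm², $E_L \approx 132$ mJ:

```{r surrogate}
w <- generate_waveform()
unlist(hemodynamic_indices(w))
```

The surrogate has no inertia, no leaflet dynamics and no flow
oscillations after closure; it exists to exercise the indices and event
logic with physiologically shaped inputs, not to reproduce any specific
simulation.

## Multi-criteria case scoring

Six cases — the three laws crossed with the two architectures — are
compared on twelve criteria: ex vivo fitting error, opening orifice
area, opening and closing durations, forward and regurgitation flow,
closed-state strain and stress variation between the belly and top-center
leaflet regions, RF, TPG, EOA and energy loss. Each criterion is min-max
normalized across the cases with its registered direction (best value 1,
worst 0); the twelve scores are summed and the cases ranked.

Two conventions required decisions:

* **Variation** is the *absolute* belly/top-center difference. The
  published worked example happens to be positive, but circumferential
  architectures load the top-center region above the belly, and only the
  absolute value reproduces the published stress-variation scores.
* **Rounding**: published score tables print two decimals, and their
  totals equal the sums of the printed entries; `build_score_table()`
  therefore rounds scores half-up to two decimals before totaling by
  default, with full precision available via `round_scores = FALSE` (the
  ranking is identical here either way). If a criterion's values are all
  equal, every case scores 1 — no information, no penalty.

Three criteria (opening orifice, forward flow, regurgitation flow) may be
supplied pre-normalized because their raw six-case vectors are not
published; the other nine are normalized from raw metrics.

```{r scoring}
st <- av_reference_score_table()
st$totals
st$rank
```

## Numerical choices and problem sizes

* Plane-stress pressure elimination: analytic, residual
  $|\sigma_{33}| < 10^{-10}$ kPa (bisection cross-check in tests).
* Finite-difference hyperelasticity oracle: central differences, step
  $10^{-6}$ on deformation-gradient entries, relative tolerance
  $10^{-5}$ over random volume-preserving states.
* Calibration: loss tolerance near machine precision (`factr = 100`),
  5000 evaluations per start; 25-point protocols for recovery studies;
  noise studies use 2 % multiplicative noise.
* Harmonic solves: sparse direct solve, residual below $10^{-10}$;
  convergence studies use 9/17/33-point structured fixtures.
* Windkessel: exact exponential stepping; surrogate cycles sample at
  0.5 ms.
* Test and verification problem sizes (structured meshes up to 33², 200
  noisy fitting replicates, 100 random states per law) keep the entire
  suite at interactive runtimes while leaving every numerical tolerance
  strict.

## Known limitations

* The constitutive module covers incompressible plane-stress membrane
  response; there is no 3D finite-element stress analysis, no
  viscoelasticity and no compressible variant.
* FD1's point Dirichlet constraints concentrate the potential near the
  commissures; the continuum problem is ill-posed in the limit, so FD1
  fields should be read as discrete constructions.
* The surrogate waveform generator is phenomenological (see above);
  conclusions about real valves require measured or FSI waveforms.
* The scoring scheme weights all criteria equally and propagates no
  uncertainty into the ranking.
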