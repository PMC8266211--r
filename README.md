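# valvemech

Constitutive modelling, rule-based fiber architecture, Windkessel
afterload, hemodynamic indices and multi-criteria scoring for aortic
valve leaflet mechanics.

## What it is for

Choosing a leaflet material model and a collagen fiber architecture is a
prerequisite of any aortic valve (AV) simulation, and the choice changes
the predicted valve dynamics. `valvemech` implements the desk-scale
computational chain a cardiovascular-biomechanics group uses to make and
defend that choice:

* three anisotropic, incompressible hyperelastic strain-energy functions
  (**W1** exponential matrix + exponential fiber, **W2** coupled
  exponential, **W3** neo-Hookean matrix + exponential fiber), with
  stress tensors, invariants, Piola/Cauchy conversion, and the analytic
  incompressible plane-stress planar-biaxial response;
* bound-constrained least-squares **calibration** of the laws to planar
  biaxial stretch–stress data, with multi-start optimization, pooled
  R², per-sample RMSE and cross-sample aggregation;
* **rule-based fiber fields** on triangulated leaflet surfaces: a
  body-fitted architecture (FD1, point constraints at the commissures)
  and a circumferential one (FD2, attachment-edge constraints), both as
  normalized gradients of harmonic potentials solved with a cotangent
  Laplacian;
* a **three-element Windkessel** afterload
  (`C dP_Wk/dt + P_Wk/R_p = Q`, `P_Ao = Q R_c + P_Wk`) integrated with
  exact exponential steps;
* transvalvular **hemodynamic indices**: regurgitant fraction, mean
  systolic pressure gradient, effective orifice area
  `EOA = Q_rms / (51.6 sqrt(dP/rho))`, and left-ventricular energy loss
  `E_L = 0.1333 ∫ (P_Ao − P_LV) Q dt`;
* the **min-max multi-criteria scoring** that normalizes twelve
  performance criteria across the six law/architecture cases (best = 1,
  worst = 0), totals them and ranks the cases;
* **synthetic-data generators** for every input: stress-controlled
  equibiaxial datasets (peak stress from Laplace's law), a lumped
  valve–Windkessel surrogate cycle waveform, and labelled idealized
  leaflet meshes.

The 3D immersed-boundary fluid–structure solver that produces real valve
waveforms is out of scope; its outputs are consumed as data.

## Worked example

Score the six constitutive-law/fiber-architecture cases from the bundled
comparative-study metrics and rank them:

```r
library(valvemech)
st <- av_reference_score_table()
print(st)
#>                    W1FD1 W2FD1 W3FD1 W1FD2 W2FD2 W3FD2
#> ex_vivo_fitting     1.00  0.95  0.00  1.00  0.95  0.00
#> opening_orifice     0.72  0.00  1.00  0.92  0.96  0.56
#> opening_duration    1.00  0.00  1.00  0.00  1.00  0.50
#> closing_duration    1.00  0.63  0.00  0.88  0.88  1.00
#> forward_flow        1.00  0.92  0.23  0.10  0.00  0.06
#> regurgitation_flow  0.56  0.86  0.00  0.86  1.00  0.74
#> strain_variation    0.56  0.81  0.00  0.88  1.00  0.00
#> stress_variation    1.00  0.53  0.00  0.93  0.42  0.72
#> RF                  0.83  1.00  0.33  0.95  0.97  0.00
#> TPG                 0.34  0.00  1.00  0.75  0.44  0.62
#> EOA                 0.35  0.04  1.00  0.43  0.00  0.23
#> EL                  0.80  0.80  0.76  1.00  0.92  0.00
#> Total               9.16  6.54  5.32  8.70  8.54  4.43
#> rank: W1FD1 > W1FD2 > W2FD2 > W2FD1 > W3FD1 > W3FD2
```

Each row is one criterion min-max scaled across the cases (1 = best,
0 = worst, direction per `criterion_directions()`); the totals say that
the doubly-exponential law with the body-fitted fiber architecture
(W1FD1) is the preferred combination, and the linear-cross-fiber law with
circumferential fibers (W3FD2) the poorest.

Calibrate a law to synthetic biaxial data and recover its parameters:

```r
p  <- porcine_leaflet_params("W1")          # published averaged values
d  <- generate_biaxial(p, biaxial_protocol(n_points = 25))
fit_biaxial("W1", d, restarts = 5, seed = 1)
#> <biaxial_fit> W1 on synthetic: RMSE 2.315e-11 kPa, R^2 1.0000
#>   C10   C01    k1    k2
#>  1.21  7.99 24.23 57.62
```

Generate a surrogate cycle and compute its hemodynamic indices:

```r
w <- generate_waveform()
round(unlist(hemodynamic_indices(w)), 2)
#> RF_percent   TPG_mmHg    EOA_cm2      EL_mJ
#>       8.98       5.34       3.25     132.02
```

A regurgitant fraction near 9 %, a mean systolic gradient of ~5 mmHg, an
effective orifice area of ~3.3 cm² and an energy loss of ~130 mJ are all
inside the physiological range spanned by published valve FSI studies.

See the vignette (`vignettes/valve-model-comparison.Rmd`) for the models,
conventions and numerical choices in full.

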