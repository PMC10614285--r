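# kinesens

Variance-based global sensitivity analysis of occupant kinematics in
vehicle braking, built around the multiplicative dimensional reduction
method (M-DRM).

Occupant safety models are usually run at nominal human characteristics,
yet volunteer braking experiments show large between-subject variability.
`kinesens` quantifies how much of the variance in kinematic response
metrics — peak forward displacement of head and T1, average vertical
displacement of each — is attributable to seven varied characteristics:
two spinal-alignment shape scores, neural delay, muscle PCSA, adipose and
passive-muscle tissue stiffness, and skin stiffness.

## What it computes

For a response $h(\mathbf{x})$ of $n$ parameters, M-DRM uses the
multiplicative approximation
$h(\mathbf{x}) \approx h(\mathbf{c})^{1-n} \prod_i h(x_i, \mathbf{c}_{-i})$
around a shared cut-point $\mathbf{c}$, so each parameter needs only
one-dimensional Gauss integrals

$$\rho_i = \sum_{j=1}^{N} w_{ij}\,h(x_{ij}, \mathbf{c}_{-i}),\qquad
\theta_i = \sum_{j=1}^{N} w_{ij}\,h(x_{ij}, \mathbf{c}_{-i})^2,$$

with nodes and weights matched to each parameter's distribution
(Gauss–Hermite for normal, Gauss–Legendre for uniform, log-space
Gauss–Hermite for lognormal). The primary sensitivity index is the
normalised variance inflation

$$S_i = \frac{\theta_i/\rho_i^2 - 1}{\sum_k \left(\theta_k/\rho_k^2 - 1\right)},$$

so $\sum_i S_i = 1$ and equal sensitivity gives exactly $1/n$. Sharing the
nominal run across parameters, 7 parameters at $N = 5$ Gauss points cost
$n(N-1)+1 = 29$ model evaluations.

Around that estimator the package provides the full study pipeline:

* **spine** — sagittal vertebral-landmark spines, signed segment angles
  (lumbar lordosis, thoracic kyphosis, cervical lordosis), and the
  iterative joint-rotation algorithm that realigns a template spine to
  target angles and C7–sacrum offset;
* **shapemodel** — PCA shape model over measurement-node coordinates,
  spine generation from PC scores;
* **distributions** — pooled coefficients of variation (two-stage,
  unweighted), quartile-based normal/lognormal fits, the seven default
  parameter specifications;
* **mdrm** — quadrature rules, the 29-run design, moments, indices, and
  the multiplicative response surrogate;
* **surrogate** — a deterministic delayed-PD double-inverted-pendulum
  occupant (synthetic; stands in for an FE body model) plus a pick-freeze
  Monte-Carlo Sobol reference estimator;
* **metrics** — first-peak forward displacement and average vertical
  displacement per body;
* **pipeline** — `run_pipeline()` orchestrating everything with a seeded
  synthetic cohort, plus a thin `exec/kinesens` command-line front end.

## Worked example

```r
library(kinesens)

meas   <- generate_fixture_population(36, seed = 1) # synthetic cohort
spines <- align_population(meas)                    # realigned template spines
shape  <- fit_shape_model(spines)
shape
#> <shape_model> 23 levels, 2 PCs (of 36), trained on 36 spines
#>   score SDs (mm): 65.83, 45.04; explained: 66.1%, 30.9%

params <- build_parameter_set()
design <- build_design(params, n_points = 5)
design
#> <mdrm_design> 7 parameters x 5 Gauss points, 29 runs (shared nominal)

man <- run_pipeline(pipeline_config(out_dir = tempfile(), seed = 1))
man$results$sensitivity$head_peak_fwd_mm
#> <sensitivity_result> metric head_peak_fwd_mm, h0 = 349
#>      parameter      rho    theta      S
#>      spine_pc1 349.0595 121855.0 0.0026
#>      spine_pc2 349.2667 122099.7 0.0238
#>   neural_delay 349.1679 121924.1 0.0012
#>    muscle_pcsa 353.6685 129699.5 0.9518
#>  adipose_props 349.1360 121942.5 0.0098
#>   muscle_props 349.1360 121942.5 0.0098
#>        skin_mu 348.7561 121635.1 0.0009

influential(man$results$sensitivity$head_peak_fwd_mm)  # S > 1/7
#> [1] "muscle_pcsa"
```

Reading the output: `h0` is the nominal-run head peak (349 mm, reached
around 0.5 s into the 10 m/s², 1.3 s braking pulse); `rho`/`theta` are each
parameter's cut mean and mean square; `S` is the share of response variance
the parameter explains alone. On the shipped surrogate the muscle PCSA
factor dominates the forward peak (S ≈ 0.95), with spinal alignment a
distant second — a property of the surrogate's mechanics, with the
directional behaviour (stronger muscles and more reclined spines both
reduce the forward peak) enforced and tested.

The same stages are scriptable from a shell:

```sh
Rscript exec/kinesens run --out-dir out/ --seed 1
Rscript exec/kinesens build-design --n-points 5 --out design.csv
```

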