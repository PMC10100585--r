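# solvmap

Monte Carlo **image solvability maps** for tomographic reconstruction.

## The problem

In computed tomography the acquisition is often incomplete: the detector may
be too small to see the whole object (projections truncated at both ends —
the *interior problem*), or a non-standard scan may under-sample some
directions. Classical diagnostics treat the discrete imaging model as a
linear system *A X = P* and ask whether it is solvable as a whole: the
condition number σ_max/σ_min of *A* tells you if the *entire* image is
stable, and the diagonal of the Moore–Penrose projector *A⁺A* marks the
individual unknowns a generalized solution recovers (a diagonal entry of 1 =
recoverable pixel). Both need the dense SVD of *A*, which is hopeless at
realistic sizes, and neither says anything about the algorithm you will
actually run.

`solvmap` implements a practical, algorithm-aware alternative. Simulate many
random ellipse phantoms *X⁽ᵐ⁾*, project, add Poisson noise, reconstruct each
with the algorithm under study, and average the squared-error images:

```
E(X⁽ᵐ⁾)_i = (x_i − x_i^true)²,      Map = (1/n) Σ_m E(X⁽ᵐ⁾)
```

The map grades every pixel: small values mark pixels the geometry/algorithm
pair reconstructs stably, large values mark unsolvable regions. For display,
values are compressed by `v ↦ 1 − exp(−20 v)`, mapping [0, ∞) to [0, 1).

The package provides:

* a parallel-beam geometry model with asymmetric truncated detectors, an
  extended virtual detector for the unmeasured bins, and the
  angular-coverage (Kirillov) ROI predictor — the pixels through which every
  line over the 180° span is measured;
* an exact Siddon ray-driven projector (compiled, sparse system matrix;
  back-projection is the literal transpose, so the pair is an exact adjoint);
* a random ellipse phantom generator with the dual-resolution protocol that
  avoids the *inverse crime*: phantoms and data live on a 3× finer grid and
  detector, noise is added, then 3 adjacent bins are averaged into each
  reconstruction-scale bin;
* gradient-descent (GD) and ML-EM solvers, each optionally with
  finite-support enforcement and/or the *truncation modification* (replacing
  unmeasured bins by the current forward projection so they exert no
  data-fit force — the naive alternative treats them as zeros);
* the Monte Carlo driver with per-phantom seeding, checkpoint/resume, and
  TIFF/PNG/JSON outputs, plus a thin CLI (`inst/cli/solvmap`);
* the dense SVD oracle (`build_dense_matrix`, `condition_number`,
  `pinv_solvability_map`) for small systems, used to validate the Monte
  Carlo maps.

## Worked example

A reduced-scale interior-problem experiment — 64×64 reconstruction, an
asymmetric 53-bin detector (offset +19 pixels), 90 views over 180°, 50
random phantoms — comparing naive GD/ML-EM against their
truncation-modified versions:

```r
library(solvmap)

cfg <- run_profile("test", truncated = TRUE, base_seed = 1,
                   variants = list(variant_spec("GD"),
                                   variant_spec("GD", trunc_mod = TRUE),
                                   variant_spec("MLEM"),
                                   variant_spec("MLEM", trunc_mod = TRUE)))
rep <- run_experiment(cfg)
print(rep)
#> run_report: 50 phantoms, 4 variants, 58.6 s
#>   variant algorithm support trunc_mod  n       min     max
#> 1      GD        GD   FALSE     FALSE 50 3.488e-04 2.92422
#> 2    GD+T        GD   FALSE      TRUE 50 7.036e-05 0.07566
#> 3    MLEM      MLEM   FALSE     FALSE 50 1.130e-48 3.65436
#> 4  MLEM+T      MLEM   FALSE      TRUE 50 2.142e-32 0.11564
```

Reading the table: with truncated data the naive solvers, which treat the
unmeasured bins as zeros, produce map maxima of ~2.9 (GD) and ~3.7 (ML-EM) —
squared errors of order 1 on a [0, 1]-valued image, i.e. whole regions are
not reconstructed at all. The truncation modification shrinks the maxima by
a factor of ~30–40. Rerunning with `truncated = FALSE` (a 93-bin detector
that sees the whole object) drops the naive maxima another three orders of
magnitude (~1e-3): the same algorithms are stable everywhere once the data
are complete, and the map minima stay strictly positive — the noise floor
left by Poisson noise and the deliberate fine/coarse model mismatch.

Per-pixel structure is in `rep$maps[["GD+T"]]$values`; `rep$roi` holds the
angular-coverage ROI, inside which errors concentrate near the map minimum.

The dense oracle cross-checks the Monte Carlo notion on toy systems:

```r
g   <- make_geometry(image_grid(24), detector(21, 1, 7), view_set(24, 0, 7.5))
sys <- build_dense_matrix(projection_operator(g))
condition_number(sys)$infinite        # TRUE: underdetermined truncated scan
range(pinv_solvability_map(sys))      # 0.233 ... 1.000
```

Pixels with diag(A⁺A) near 1 are exactly the pixels the Monte Carlo map
grades as stable (Spearman correlation ≈ 0.88 between 1 − diag(A⁺A) and the
map in the bundled experiment).

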