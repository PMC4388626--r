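# balancedcs

Balanced sparse models for tight-frame compressed-sensing MRI in R.

Compressed-sensing MRI reconstructs an image `x` from undersampled
k-space data `y = U F x + η` by exploiting sparsity under a transform.
For a redundant tight frame `Ψ` (with `Ψ*Ψ = I` but `ΨΨ* ≠ I`) the
classical *analysis* prior (`‖Ψx‖₁`) and *synthesis* prior (`‖α‖₁`,
`x = Ψ*α`) are genuinely different models. This package implements the
**constrained balanced model**, which spans both:

    x̂ = Ψ*α̂,   α̂ = argmin_α  λ‖α‖₁ + (β/2)‖(I − ΨΨ*)α‖₂²
                 s.t.  ‖y − U F Ψ* α‖₂² ≤ σ²

reparameterized by `γ = ρ/(ρ+β) ∈ [0,1]`: `γ = 0` is the analysis
model, `γ = 1` the synthesis model, and intermediate values balance the
two. The core solver, **C-SALSA-B** (`csalsa_b()`), is ADMM applied to
the constrained form with an *exact closed-form* coefficient update
(valid precisely because every frame here is Parseval-tight and the DFT
is unitary); **ADMM-B** (`admm_b()`) and accelerated proximal gradient
(`apg()`) baselines solve the unconstrained relaxation. Reconstruction
quality is measured by the relative ℓ2-norm error
`RLNE = ‖x̂ − x‖₂ / ‖x‖₂`.

Included building blocks:

* **Frames** — shift-invariant wavelet (`make_sidwt_frame()`, redundancy
  `3·levels + 1`), orthogonal wavelet (`make_orthogonal_dwt_frame()`),
  translation-invariant DCT (`make_tidct_frame()`); all Parseval-tight
  and verified at construction.
* **k-space** — variable-density Cartesian masks (`generate_mask()`),
  unitary Fourier measurement with complex Gaussian noise (`measure()`),
  zero-filled adjoint (`zero_fill_adjoint()`).
* **Synthetic data** — complex piecewise-smooth phantoms
  (`make_phantom()`) and reproducible fixtures (`make_fixture()`).
* **Experiments** — balancing-parameter sweeps (`sweep_gamma()`),
  sampling-ratio sweeps (`sweep_sampling()`), solver comparisons
  (`compare_algorithms()`), all returning tibbles with ggplot2
  companions, plus broom-style `tidy()`/`glance()`/`autoplot()` methods
  for solver results and a command-line front end
  (`inst/cli/balancedcs`).

## Worked example

```r
library(balancedcs)

fx <- make_fixture()                       # 64x64 Shepp-Logan phantom,
                                           # 40% variable-density k-space
fr <- make_sidwt_frame(c(64, 64), "db4", 3)

finals <- sapply(c(0, 0.5, 1), function(g) {
  res <- csalsa_b(fx$kdata, fr,
                  solver_config(gamma = g, max_iter = 150, tol = 1e-6),
                  x_true = fx$image)
  glance(res)$rlne
})
round(setNames(finals, c("analysis", "balanced", "synthesis")), 4)
#> analysis  balanced synthesis
#>   0.1454    0.1612    0.1830
```

The analysis end (`γ = 0`) reconstructs with the lowest error, the
synthesis end (`γ = 1`) with the highest, and the balanced model sits
between — the characteristic ordering for redundant tight frames. On an
orthogonal wavelet frame the same sweep is exactly flat (the three
models provably coincide). Comparing solvers on the same fixture:

```r
cmp <- compare_algorithms(fx, fr)
cmp$summary
#> # A tibble: 3 × 4
#>   solver   iterations_to_threshold final_rlne threshold
#>   <chr>                      <int>      <dbl>     <dbl>
#> 1 csalsa_b                      15      0.161     0.169
#> 2 admm_b                        NA      0.211     0.169
#> 3 apg                           NA      0.175     0.169
```

C-SALSA-B reaches the common error threshold (1.05× the best final RLNE)
in the fewest iterations; here the baselines never reach it within their
iteration budget. `plot_convergence(cmp)`, `plot_gamma_sweep()` and
`plot_sampling_sweep()` draw the corresponding figures.

From a shell:

```sh
Rscript inst/cli/balancedcs reconstruct --size 64 --fraction 0.4 \
    --frame sidwt --solver csalsa_b --gamma 0 --out-dir out/
Rscript inst/cli/balancedcs sweep-gamma --frame dwt --out-dir out/
```

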