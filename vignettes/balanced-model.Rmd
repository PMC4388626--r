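---
title: "The balanced sparse model for tight-frame CS-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The balanced sparse model for tight-frame CS-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(balancedcs)
```

## The reconstruction problem

MRI scanners acquire data in k-space, the 2-D Fourier domain of the image.
Acquisition time is proportional to the number of k-space lines collected,
so compressed-sensing MRI undersamples k-space and reconstructs the image
by exploiting its sparsity under a transform. The measurement model is

$$ y = U F x + \eta, $$

with $x \in \mathbb{C}^N$ the image, $F$ the unitary 2-D DFT, $U$ a binary
restriction to $M < N$ sampled locations, and $\eta$ complex Gaussian
noise. Reconstruction is ill-posed and needs a sparsity prior.

When the sparsifying transform is a **tight frame** — an analysis operator
$\Psi \in \mathbb{C}^{D \times N}$ with $D > N$, $\Psi^*\Psi = I$ but
$\Psi\Psi^* \neq I$ — there are two classical priors. The *analysis model*
penalizes $\|\Psi x\|_1$, searching over images; the *synthesis model*
penalizes $\|\alpha\|_1$ with $x = \Psi^*\alpha$, searching over the larger
coefficient space. They coincide only for invertible (orthogonal) $\Psi$.
The **balanced model** bridges them by penalizing the distance of the
coefficients from the range of $\Psi$ (the set of canonical coefficients
$\alpha_c = \Psi x$):

$$ \hat{x} = \Psi^*\hat\alpha, \qquad
   \hat\alpha = \arg\min_\alpha \; \lambda\|\alpha\|_1 +
   \tfrac{\beta}{2}\|(I - \Psi\Psi^*)\alpha\|_2^2
   \quad \text{s.t.} \quad \|y - U F \Psi^* \alpha\|_2^2 \le \sigma^2. $$

With $\beta = 0$ this is the synthesis model; as $\beta \to \infty$ the
coefficients are forced into the range of $\Psi$ and the problem reduces
exactly to the analysis model. The package exposes the reparameterization

$$ \gamma = \frac{\rho}{\rho + \beta} \in [0, 1], $$

so one knob moves continuously from analysis ($\gamma = 0$) through
balanced ($\gamma = 1/2$) to synthesis ($\gamma = 1$); both endpoints are
handled exactly, not by a large finite $\beta$.

## The C-SALSA-B solver

`csalsa_b()` applies ADMM to the constrained problem directly, avoiding
the delicate choice of a data-fidelity weight that the unconstrained
relaxation needs. With the splitting $z = \alpha$ and an exact equality
constraint $y = UF\Psi^*\alpha$ relaxed through a measurement-domain
multiplier $h$, the augmented Lagrangian

$$ L_{\mu,\rho}(\alpha, z, h, d) = \lambda\|z\|_1 +
   \tfrac{\beta}{2}\|(I-\Psi\Psi^*)\alpha\|^2 +
   \tfrac{\mu}{2}\|UF\Psi^*\alpha - y - h\|^2 +
   \tfrac{\rho}{2}\|\alpha - z - d\|^2 $$

is minimized alternately. The coefficient subproblem has the closed-form
unique minimizer

$$ \alpha^{+} = \tfrac{\mu}{\mu+\rho}\,\Psi F^*U^*(y+h) + \gamma(z+d) +
   \Psi F^*\!\left[(1-\gamma)I - \tfrac{\mu}{\mu+\rho}U^*U\right]\!
   F\Psi^*(z+d), $$

which is exact *because* the frame is Parseval-tight and $U^*U$ is a 0/1
diagonal in the unitary Fourier basis: the normal-equation operator then
block-diagonalizes over range($\Psi$) and its complement, and the Fourier
factor diagonalizes the in-range block. `alpha_update()` implements this
formula; `subproblem_oracle()` solves the same normal equations by
conjugate gradient and is used in the tests as an independent check (they
agree to machine precision across the whole $\gamma$ grid, including both
endpoints). The $z$ update is complex magnitude soft-thresholding
$\mathcal{T}_{\lambda/\rho}(\alpha^{+} - d)$, and both multipliers take
gradient steps with sizes $\delta_h$, $\delta_d$.

The two baselines solve the unconstrained relaxation
$\lambda\|z\|_1 + \frac{\beta}{2}\|(I-\Psi\Psi^*)\alpha\|^2 +
\frac{\delta}{2}\|y - UF\Psi^*\alpha\|^2$: `admm_b()` by the same
splitting (its coefficient subproblem is the same quadratic with
$(\mu, y+h) \to (\delta, y)$), and `apg()` by FISTA-type accelerated
proximal gradient with exact Lipschitz constant $L = \beta + \delta$ for a
Parseval frame and unitary DFT. `apg()` refuses $\gamma = 0$, where
$\beta$ is infinite and the smooth part has no gradient.

### Parameters and defaults

| parameter | meaning | default |
|---|---|---|
| `lambda` | $\ell_1$ weight (dimensionless) | 0.05 (C-SALSA-B), 0.01 (ADMM-B), 0.005 (APG) |
| `gamma` | balance, 0 = analysis, 1 = synthesis | 0.5 |
| `rho`, `mu` | ADMM penalties | 1 |
| `delta_h`, `delta_d` | multiplier step sizes | 1 |
| `delta_fid` | fidelity weight $\delta$ of the unconstrained baselines | 1 |
| `sigma_sq` | constraint level $\sigma^2$ | 0 |
| `max_iter`, `tol` | iteration cap, relative-change tolerance | 100, 1e-5 |

The solver defaults follow the parameter set commonly used with this
family of algorithms on T2-weighted brain data; they were not re-tuned per
fixture. The `relax` field exposes optional ADMM over-relaxation for
`admm_b()` (default 1 — off), and `monotone` selects the restart variant
of APG (default on; plain momentum is available behind the same flag).

### Numerical choices

* **Initialization**: $z_1 = \Psi(F^*U^*y)$ (the zero-filled
  reconstruction's canonical coefficients), $d_1 = 0$, $h_1 = 0$. Any
  bounded start converges; the warm start matches practice.
* **Stopping**: the constraint test
  $\|y - UF\Psi^*\alpha\|^2 \le \sigma^2$ alone can never fire in
  noiseless simulation ($\sigma^2 = 0$ is only reached in the limit), so
  it is combined with a relative-change test on $\hat{x}$: the solver
  stops when the relative change drops below `tol` *and*, if
  `sigma_sq > 0`, the constraint is met; `max_iter` always bounds the run.
* **Complex soft-thresholding** shrinks magnitudes and preserves phase;
  on real data it reduces to the usual signed shrinkage.
* **Divergence guard**: a non-finite iterate raises an error naming the
  likely parameter culprits instead of returning garbage.
* **Frame normalization**: all frames are constructed Parseval-tight
  (per-level $1/\sqrt 2$ rescaling for the undecimated wavelet, $1/p$ for
  the $p^2$-fold shifted DCT) and verified at construction on random
  inputs; a frame failing the tightness check is rejected, because the
  closed-form update would silently stop being a minimizer. Periodic
  boundary extension is used throughout — symmetric extension would break
  exact tightness.
* **Coefficient ordering** is subband-major (finest detail subbands
  first, lowpass last; shift-major for the TIDCT), column-major within a
  subband, and only needs to be self-consistent: solvers treat
  coefficients as flat vectors.

## Frames provided

* `make_sidwt_frame()` — shift-invariant (undecimated) separable wavelet,
  redundancy $3\,\text{levels} + 1$, implemented by FFT-domain transfer
  functions of the à-trous filter cascade. Default Daubechies 4-tap
  filter, 3 levels: a standard choice for piecewise-smooth MR images;
  the filter and depth are configurable.
* `make_orthogonal_dwt_frame()` — decimated orthogonal wavelet, $D = N$.
  For this frame $\Psi\Psi^* = I$, the closed-form update is provably
  independent of $\gamma$, and the three models coincide — the package's
  tests confirm the traces are *identical*, not merely close.
* `make_tidct_frame()` — orthogonal DCT over all cyclic shifts of a patch
  grid (redundancy $p^2$); with patch = image it degenerates to the plain
  orthogonal 2-D DCT.

The frame interface (`analysis`/`synthesis`/`range_projection` on a
`frame_operator`) is the extension point for adaptive transforms
(directional wavelets, contourlets), which are not implemented here.

## Synthetic data

Scanner images are not distributed with the package, so experiments run
on synthetic phantoms from `make_phantom()`: the Shepp-Logan head
phantom, a randomized piecewise-smooth ellipse "brain", and a
water-phantom-style disk grid, each optionally given a smooth random
phase (low-order polynomial surface) to mimic the slowly varying phase of
real acquisitions. All are piecewise smooth with sharp edges and mild
internal intensity ramps, hence compressible: at least 90% of the wavelet
energy sits in at most 10% of the coefficients — the $S \ll N$ premise
of sparse recovery. `generate_mask()` draws variable-density Cartesian
patterns with a fully sampled center block (default 8% of each edge) and
a polynomially decaying density (exponent 4), the standard emulation of
published undersampling patterns; the exact published pattern generator
is not specified anywhere, so this is a stand-in, not a reproduction.

What the phantoms do *not* model: coil sensitivity profiles, relaxation
contrast, non-Cartesian trajectories, and structured (non-Gaussian)
noise. Passing tests on these fixtures therefore demonstrate the
correctness of the operators and solvers and the qualitative model
ordering, not clinical image quality.

## A worked comparison

Problem sizes here and in the tests are 64×64 with 40% sampling (the
package's desk-scale default; 256×256 works identically through the same
functions and is the size used by the command-line experiment runners'
documentation examples).

```{r ordering}
fx <- make_fixture()   # 64x64 Shepp-Logan, 40% variable-density, seed 1234
fr <- make_sidwt_frame(c(64, 64), "db4", 3)

finals <- sapply(c(0, 0.5, 1), function(g) {
  res <- csalsa_b(fx$kdata, fr, solver_config(gamma = g, max_iter = 150,
                                              tol = 1e-6),
                  x_true = fx$image)
  glance(res)$rlne
})
round(stats::setNames(finals, c("analysis", "balanced", "synthesis")), 4)
```

The analysis end achieves the lowest error and the synthesis end the
highest, with the balanced model in between — the ordering that motivates
the balanced formulation as a unified framework. On an orthogonal frame
the same sweep is exactly flat.

```{r compare}
cmp <- compare_algorithms(fx, fr)
cmp$summary
```

C-SALSA-B reaches the common RLNE threshold (1.05 times the best final
error) in the fewest iterations. The iteration-count comparison uses this
relative threshold rather than fixed counts because absolute counts
depend on the data.

```{r plot, eval = requireNamespace("ggplot2", quietly = TRUE)}
plot_convergence(cmp)
```

## Known limitations

* Tight frames only: frames failing the Parseval check are rejected, and
  non-tight dictionaries are out of scope by construction.
* The qualitative analysis-vs-synthesis ordering is a statistical
  property of realistic problem sizes; on very small images (32×32) at
  aggressive undersampling single mask draws can invert it, which is why
  ordering checks aggregate medians over mask seeds at 64×64.
* The empirical convergence comparison is exactly that — empirical; no
  rate proofs are provided.
* Binary Cartesian masks only; no partial-Fourier or non-Cartesian
  sampling, no parallel-imaging coil model.
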