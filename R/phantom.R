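#' Synthetic phantoms
#'
#' Piecewise-smooth complex test images standing in for scanner data:
#' the classic Shepp-Logan head phantom, a randomized piecewise-smooth
#' "brain-like" ellipse phantom, and a water-phantom-style grid of disks.
#' All are sparse under wavelet transforms (most energy in few
#' coefficients), which is the premise of the sparse reconstruction
#' models. Magnitudes are normalized to `contrast_range`; an optional
#' smooth random phase emulates the slowly varying phase of real MR
#' images.
#'
#' @name phantoms
NULL

# Modified Shepp-Logan ellipse table: intensity, a, b, x0, y0, angle(deg).
.shepp_logan_ellipses <- matrix(c(
   1.0, 0.69,  0.92,  0.0,   0.0,    0,
  -0.8, 0.6624, 0.874, 0.0, -0.0184, 0,
  -0.2, 0.11,  0.31,  0.22,  0.0,  -18,
  -0.2, 0.16,  0.41, -0.22,  0.0,   18,
   0.1, 0.21,  0.25,  0.0,   0.35,   0,
   0.1, 0.046, 0.046, 0.0,   0.1,    0,
   0.1, 0.046, 0.046, 0.0,  -0.1,    0,
   0.1, 0.046, 0.023, -0.08, -0.605, 0,
   0.1, 0.023, 0.023, 0.0,  -0.606,  0,
   0.1, 0.023, 0.046, 0.06, -0.605,  0
), ncol = 6, byrow = TRUE)

.render_ellipses <- function(ellipses, shape, ramp = 0) {
  N1 <- shape[1]; N2 <- shape[2]
  xg <- matrix(rep(seq(-1, 1, length.out = N2), each = N1), N1, N2)
  yg <- matrix(rep(seq(1, -1, length.out = N1), times = N2), N1, N2)
  img <- matrix(0, N1, N2)
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    phi <- e[6] * pi / 180
    xr <- cos(phi) * (xg - e[4]) + sin(phi) * (yg - e[5])
    yr <- -sin(phi) * (xg - e[4]) + cos(phi) * (yg - e[5])
    inside <- (xr / e[2])^2 + (yr / e[3])^2 <= 1
    # mild smooth intensity ramp inside each structure
    shade <- 1 + ramp * xr / e[2]
    img[inside] <- img[inside] + e[1] * shade[inside]
  }
  img
}

.smooth_random_phase <- function(shape, seed, scale = 0.5 * pi) {
  withr::with_seed(seed + 7L, {
    co <- stats::rnorm(6)
  })
  N1 <- shape[1]; N2 <- shape[2]
  xg <- matrix(rep(seq(-1, 1, length.out = N2), each = N1), N1, N2)
  yg <- matrix(rep(seq(-1, 1, length.out = N1), times = N2), N1, N2)
  ph <- co[1] * xg + co[2] * yg + co[3] * xg * yg +
    co[4] * xg^2 + co[5] * yg^2 + co[6] * xg^2 * yg
  ph / max(abs(ph)) * scale
}

#' Generate a synthetic complex phantom
#'
#' @param kind `"shepp_logan"`, `"piecewise_smooth_brain"` or
#'   `"water_phantom_disks"`.
#' @param shape integer vector `c(N1, N2)`.
#' @param contrast_range magnitude range after normalization.
#' @param edge_density multiplier on the number of random structures
#'   (brain / disk kinds; ignored for the fixed Shepp-Logan anatomy).
#' @param phase_model `"zero"` (purely real image) or `"smooth_random"`
#'   (low-order polynomial phase surface).
#' @param seed integer seed; the phantom is reproducible given
#'   `(kind, shape, ..., seed)`.
#' @return complex image matrix with magnitude in `contrast_range`.
#' @export
make_phantom <- function(kind = c("shepp_logan", "piecewise_smooth_brain",
                                  "water_phantom_disks"),
                         shape = c(64, 64), contrast_range = c(0, 1),
                         edge_density = 1,
                         phase_model = c("zero", "smooth_random"),
                         seed = 1L) {
  kind <- match.arg(kind)
  phase_model <- match.arg(phase_model)
  shape <- as.integer(shape)
  mag <- switch(kind,
    shepp_logan = .render_ellipses(.shepp_logan_ellipses, shape, ramp = 0.05),
    piecewise_smooth_brain = {
      n_ell <- max(3L, as.integer(round(8 * edge_density)))
      withr::with_seed(seed, {
        ell <- cbind(stats::runif(n_ell, -0.5, 0.8),
                     stats::runif(n_ell, 0.08, 0.45),
                     stats::runif(n_ell, 0.08, 0.45),
                     stats::runif(n_ell, -0.5, 0.5),
                     stats::runif(n_ell, -0.5, 0.5),
                     stats::runif(n_ell, 0, 180))
      })
      skull <- matrix(c(1, 0.85, 0.95, 0, 0, 0,
                        -0.25, 0.78, 0.88, 0, 0, 0), ncol = 6, byrow = TRUE)
      .render_ellipses(rbind(skull, ell), shape, ramp = 0.1)
    },
    water_phantom_disks = {
      k <- max(2L, as.integer(round(3 * edge_density)))
      cent <- seq(-0.6, 0.6, length.out = k)
      ell <- do.call(rbind, lapply(cent, function(cx) {
        do.call(rbind, lapply(cent, function(cy) {
          c(0.8, 0.55 / k, 0.55 / k, cx, cy, 0)
        }))
      }))
      shell <- matrix(c(0.3, 0.9, 0.9, 0, 0, 0), ncol = 6)
      .render_ellipses(rbind(shell, ell), shape, ramp = 0.05)
    }
  )
  mag <- pmax(mag, 0)
  if (max(mag) > 0) mag <- mag / max(mag)
  mag <- contrast_range[1] + mag * diff(contrast_range)
  if (phase_model == "zero") {
    mag + 0i
  } else {
    mag * exp(1i * .smooth_random_phase(shape, seed))
  }
}

#' Generate a complete simulation fixture
#'
#' Composes [make_phantom()], [generate_mask()] and [measure()] into one
#' reproducible object. The default arguments define the frozen test
#' fixture used throughout the package's checks: a 64x64 Shepp-Logan
#' phantom with a 40% variable-density mask, no noise, seed 1234.
#'
#' @inheritParams make_phantom
#' @param sampling_fraction k-space sampling fraction.
#' @param noise_sigma per-component measurement noise standard deviation.
#' @param seed master seed; mask and noise seeds are derived from it.
#' @param pattern mask pattern, see [generate_mask()].
#' @return a `cs_fixture`: list with `image`, `mask`, `kdata` and the
#'   generating parameters.
#' @export
make_fixture <- function(kind = "shepp_logan", shape = c(64, 64),
                         sampling_fraction = 0.40, noise_sigma = 0,
                         seed = 1234L, pattern = "variable_density_2d",
                         phase_model = "zero", edge_density = 1) {
  image <- make_phantom(kind, shape, phase_model = phase_model,
                        edge_density = edge_density, seed = seed)
  mask <- generate_mask(shape, sampling_fraction, pattern = pattern,
                        seed = seed)
  kdata <- measure(image, mask, noise_sigma = noise_sigma, seed = seed + 1L)
  structure(
    list(image = image, mask = mask, kdata = kdata,
         spec = list(kind = kind, shape = shape,
                     sampling_fraction = sampling_fraction,
                     noise_sigma = noise_sigma, seed = seed,
                     pattern = pattern, phase_model = phase_model,
                     edge_density = edge_density)),
    class = "cs_fixture"
  )
}

#' @export
print.cs_fixture <- function(x, ...) {
  cat(sprintf("<cs_fixture: %s %dx%d, %.0f%% sampled, sigma = %g, seed %d>\n",
              x$spec$kind, x$spec$shape[1], x$spec$shape[2],
              100 * x$spec$sampling_fraction, x$spec$noise_sigma,
              x$spec$seed))
  invisible(x)
}
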