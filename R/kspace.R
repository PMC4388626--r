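#' Fourier measurement model
#'
#' MRI acquisition is modeled as \eqn{y = UFx + \eta}: a unitary 2-D
#' discrete Fourier transform \eqn{F} of the image, restricted by a binary
#' undersampling mask \eqn{U} to \eqn{M < N} k-space locations, plus
#' circularly symmetric complex Gaussian noise. The unitary convention
#' (\eqn{F^*F = I}, \eqn{\|F\| = 1}) matters: it makes \eqn{U^*U} a 0/1
#' diagonal projector in an orthonormal basis, which is what the solver's
#' closed-form coefficient update assumes.
#'
#' Masks are stored in centered layout (zero frequency at the grid
#' center); the unshifted FFT layout is used internally.
#'
#' @name kspace_model
NULL

.fftshift_idx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
.ifftshift_idx <- function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2))

fftshift2 <- function(x) x[.fftshift_idx(nrow(x)), .fftshift_idx(ncol(x))]
ifftshift2 <- function(x) x[.ifftshift_idx(nrow(x)), .ifftshift_idx(ncol(x))]

# Unitary 2-D DFT and inverse (zero frequency at [1,1]).
ft2 <- function(x) stats::fft(x) / sqrt(length(x))
ift2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

#' Generate a k-space undersampling mask
#'
#' Draws exactly `round(sampling_fraction * N)` sample locations on an
#' `N1 x N2` Cartesian grid. The default variable-density pattern keeps a
#' fully sampled central calibration block of
#' `center_fraction * N1 x center_fraction * N2` and draws the remaining
#' locations without replacement with probability decaying polynomially
#' with distance from the k-space center, emulating the variable-density
#' random patterns standard in CS-MRI (e.g. a 40% pattern).
#'
#' @param shape integer vector `c(N1, N2)`.
#' @param sampling_fraction fraction of k-space sampled, in (0, 1].
#' @param pattern `"variable_density_2d"`, `"uniform_random"` or `"full"`.
#' @param center_fraction edge fraction of the fully sampled center block
#'   (variable-density pattern only).
#' @param density_exponent polynomial decay exponent of the sampling
#'   density away from the center.
#' @param seed integer seed; the same seed always yields the same mask.
#' @return a `sampling_mask`: list with logical matrix `grid` (centered
#'   layout), sample count `M`, and the generation parameters.
#' @export
generate_mask <- function(shape, sampling_fraction,
                          pattern = c("variable_density_2d",
                                      "uniform_random", "full"),
                          center_fraction = 0.08, density_exponent = 4,
                          seed = 1L) {
  pattern <- match.arg(pattern)
  shape <- as.integer(shape)
  N1 <- shape[1]; N2 <- shape[2]; N <- N1 * N2
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    stop("sampling_fraction must be in (0, 1]", call. = FALSE)
  }
  M <- as.integer(round(sampling_fraction * N))
  grid <- matrix(FALSE, N1, N2)
  if (pattern == "full" || M == N) {
    grid[] <- TRUE
    M <- N
  } else if (pattern == "uniform_random") {
    withr::with_seed(seed, {
      grid[sample.int(N, M)] <- TRUE
    })
  } else {
    c1 <- max(1L, as.integer(round(center_fraction * N1)))
    c2 <- max(1L, as.integer(round(center_fraction * N2)))
    r1 <- floor(N1 / 2) + 1 + seq_len(c1) - ceiling((c1 + 1) / 2)
    r2 <- floor(N2 / 2) + 1 + seq_len(c2) - ceiling((c2 + 1) / 2)
    center <- matrix(FALSE, N1, N2)
    center[r1, r2] <- TRUE
    n_center <- sum(center)
    if (M < n_center) {
      stop("requested sampling fraction (", sampling_fraction,
           ") is smaller than the fully sampled center block; reduce ",
           "center_fraction", call. = FALSE)
    }
    k1 <- (seq_len(N1) - (floor(N1 / 2) + 1)) / (N1 / 2)
    k2 <- (seq_len(N2) - (floor(N2 / 2) + 1)) / (N2 / 2)
    d <- sqrt(outer(k1^2, k2^2, `+`)) / sqrt(2)
    w <- pmax(1 - d, 0)^density_exponent + 1e-12
    w[center] <- 0
    cand <- which(!center)
    withr::with_seed(seed, {
      extra <- sample(cand, M - n_center, prob = w[cand])
    })
    grid[center] <- TRUE
    grid[extra] <- TRUE
  }
  structure(
    list(grid = grid, M = M, sampling_fraction = M / N, shape = shape,
         pattern = pattern, center_fraction = center_fraction,
         density_exponent = density_exponent, seed = seed),
    class = "sampling_mask"
  )
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask: %dx%d, M = %d (%.1f%%), %s>\n",
              x$shape[1], x$shape[2], x$M, 100 * x$sampling_fraction,
              x$pattern))
  invisible(x)
}

#' Simulate undersampled k-space measurement
#'
#' Computes \eqn{y = UFx + \eta}: unitary 2-D DFT of the image, restricted
#' to the masked locations, plus i.i.d. complex Gaussian noise with
#' per-component standard deviation `noise_sigma`.
#'
#' @param x complex image matrix.
#' @param mask a [generate_mask()] result of matching shape.
#' @param noise_sigma per-component noise standard deviation.
#' @param seed integer seed for the noise draw (ignored when
#'   `noise_sigma = 0`).
#' @return a `kspace_data`: list with complex `samples` (length `M`, in
#'   column-major order of the masked centered grid), the `mask`, and
#'   `noise_sigma`.
#' @export
measure <- function(x, mask, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(mask, "sampling_mask"))
  if (!is.matrix(x) || !all(dim(x) == mask$shape)) {
    stop("image and mask shapes do not match", call. = FALSE)
  }
  K <- fftshift2(ft2(x))
  y <- K[mask$grid]
  if (noise_sigma > 0) {
    withr::with_seed(seed, {
      y <- y + noise_sigma * (stats::rnorm(mask$M) +
                                1i * stats::rnorm(mask$M))
    })
  }
  structure(list(samples = y, mask = mask, noise_sigma = noise_sigma),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data: M = %d samples of %dx%d grid, sigma = %g>\n",
              x$mask$M, x$mask$shape[1], x$mask$shape[2], x$noise_sigma))
  invisible(x)
}

#' Zero-filled adjoint reconstruction
#'
#' Computes \eqn{F^*U^*y}: the measured values are inserted at their
#' k-space locations, zeros elsewhere, and the inverse unitary DFT is
#' applied. This is the standard zero-filled reconstruction used both as
#' a baseline and as the solvers' warm start.
#'
#' @param kdata a [measure()] result.
#' @return complex image matrix.
#' @export
zero_fill_adjoint <- function(kdata) {
  stopifnot(inherits(kdata, "kspace_data"))
  mask <- kdata$mask
  K <- matrix(0 + 0i, mask$shape[1], mask$shape[2])
  K[mask$grid] <- kdata$samples
  ift2(ifftshift2(K))
}

# Internal: embed a masked sample vector on the unshifted k-space grid.
.embed_nc <- function(y, mask) {
  K <- matrix(0 + 0i, mask$shape[1], mask$shape[2])
  K[mask$grid] <- y
  ifftshift2(K)
}

# Internal: mask in unshifted layout (0/1), cached on first use.
.mask_nc <- function(mask) ifftshift2(mask$grid)

# Internal: forward masked unitary DFT of an image, returning the sample
# vector in the same order as measure().
.forward_masked <- function(x, mask) {
  fftshift2(ft2(x))[mask$grid]
}
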