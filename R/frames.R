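#' Tight-frame analysis/synthesis operators
#'
#' A `frame_operator` holds a paired analysis map \eqn{\Psi} (image to
#' coefficients) and synthesis map \eqn{\Psi^*} (coefficients to image)
#' for a fixed image shape. Every frame constructed by this package is
#' Parseval-tight: \eqn{\Psi^*\Psi = I} and \eqn{\|\Psi x\|_2 = \|x\|_2},
#' so \eqn{\Psi\Psi^*} is the orthogonal projector onto the range of
#' \eqn{\Psi}. Tightness is what makes the balanced solver's closed-form
#' coefficient update an exact subproblem minimizer, so each constructor
#' verifies it on random inputs and refuses to return a frame that fails.
#'
#' Coefficients are stored as a flat complex vector, subband-major
#' (detail subbands from the finest level inward, lowpass last for
#' wavelets; shift-major for the translation-invariant DCT), column-major
#' within each subband. Solvers treat coefficients as a flat vector, so
#' only self-consistency of the ordering matters.
#'
#' @name frame_operator
NULL

# Orthonormal wavelet filter taps (unit l2 norm). Names give the tap count.
.wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  db4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
  db8 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

.get_filter <- function(wavelet_name) {
  h <- .wavelet_filters[[wavelet_name]]
  if (is.null(h)) {
    stop("unsupported wavelet '", wavelet_name, "'; available: ",
         paste(names(.wavelet_filters), collapse = ", "), call. = FALSE)
  }
  h
}

# Quadrature mirror highpass: g[n] = (-1)^n h[L-1-n] (0-based), giving the
# power-complementary pair |H|^2 + |G|^2 = 2 for unit-norm orthonormal taps.
.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

new_frame_operator <- function(name, shape, D, is_orthogonal,
                               analysis_fn, synthesis_fn, params = list()) {
  structure(
    list(name = name, shape = as.integer(shape), D = as.integer(D),
         redundancy = D / prod(shape), is_orthogonal = is_orthogonal,
         analysis_fn = analysis_fn, synthesis_fn = synthesis_fn,
         params = params),
    class = "frame_operator"
  )
}

#' @export
print.frame_operator <- function(x, ...) {
  cat(sprintf("<frame_operator: %s, %dx%d image, D = %d (redundancy %.3g)%s>\n",
              x$name, x$shape[1], x$shape[2], x$D, x$redundancy,
              if (x$is_orthogonal) ", orthogonal" else ""))
  invisible(x)
}

.check_image <- function(x, frame) {
  if (!is.matrix(x) || !all(dim(x) == frame$shape)) {
    stop("image shape (", paste(dim(x), collapse = "x"),
         ") does not match frame shape (",
         paste(frame$shape, collapse = "x"), ")", call. = FALSE)
  }
}

.check_coef <- function(a, frame) {
  if (length(a) != frame$D) {
    stop("coefficient length ", length(a), " does not match frame D = ",
         frame$D, call. = FALSE)
  }
}

#' Apply the analysis operator
#'
#' Computes the canonical frame coefficients \eqn{\Psi x} of an image.
#'
#' @param x complex matrix, the image; dimensions must match the frame.
#' @param frame a [frame_operator].
#' @return complex vector of length `frame$D`.
#' @export
analysis <- function(x, frame) {
  stopifnot(inherits(frame, "frame_operator"))
  .check_image(x, frame)
  frame$analysis_fn(x)
}

#' Apply the synthesis operator
#'
#' Computes \eqn{\Psi^* a}, the image synthesized from frame coefficients.
#' For the Parseval frames built here `synthesis(analysis(x)) == x`.
#'
#' @param a complex vector of length `frame$D`.
#' @inheritParams analysis
#' @return complex matrix with the frame's image shape.
#' @export
synthesis <- function(a, frame) {
  stopifnot(inherits(frame, "frame_operator"))
  .check_coef(a, frame)
  frame$synthesis_fn(a)
}

#' Project onto the range of the analysis operator
#'
#' Applies \eqn{P = \Psi\Psi^*}, the orthogonal projector onto the set of
#' canonical coefficients. Idempotent; the identity for orthogonal frames.
#'
#' @inheritParams synthesis
#' @return complex vector of length `frame$D`.
#' @export
range_projection <- function(a, frame) {
  analysis(synthesis(a, frame), frame)
}

# Randomized construction-time contract check: perfect reconstruction and
# the Parseval identity on a handful of random complex images. Frames that
# are not tight to near machine precision are rejected because the solver's
# closed-form update is only exact for tight frames.
.validate_tightness <- function(frame, n_checks = 3, tol = 1e-9) {
  withr::with_seed(423771, {
    for (i in seq_len(n_checks)) {
      x <- matrix(stats::rnorm(prod(frame$shape)) +
                    1i * stats::rnorm(prod(frame$shape)),
                  frame$shape[1], frame$shape[2])
      a <- frame$analysis_fn(x)
      pr_err <- sqrt(sum(Mod(frame$synthesis_fn(a) - x)^2) / sum(Mod(x)^2))
      pa_err <- abs(sqrt(sum(Mod(a)^2)) - sqrt(sum(Mod(x)^2))) /
        sqrt(sum(Mod(x)^2))
      if (pr_err > tol || pa_err > tol) {
        stop("constructed frame is not Parseval-tight (reconstruction error ",
             format(pr_err), ", energy error ", format(pa_err), ")",
             call. = FALSE)
      }
    }
  })
  frame
}

# ---------------------------------------------------------------------------
# Shift-invariant (undecimated) wavelet frame via FFT transfer functions.
#
# Each subband is circular convolution with an a-trous upsampled filter,
# realized as pointwise multiplication in the Fourier domain. With the
# orthonormal lowpass/highpass pair rescaled by 1/sqrt(2) per level and
# dimension, the transfer functions satisfy sum_k |H_k|^2 = 1 pointwise,
# which gives exact tightness for periodic boundaries.
# ---------------------------------------------------------------------------

# DTFT of filter taps on the N-point frequency grid, filter upsampled 2^(l-1).
.filter_transfer <- function(h, N, level) {
  omega_idx <- (seq_len(N) - 1) * 2^(level - 1) %% N
  ks <- seq_along(h) - 1
  vapply(omega_idx, function(j) {
    sum(h * exp(-2i * pi * j * ks / N))
  }, complex(1))
}

# Build the list of 2-D subband transfer arrays for an undecimated separable
# wavelet: 3 detail bands per level plus the final lowpass, subband-major
# order finest level first, lowpass last.
.sidwt_transfers <- function(shape, h, levels) {
  g <- .qmf(h)
  N1 <- shape[1]; N2 <- shape[2]
  A1 <- rep(1 + 0i, N1); A2 <- rep(1 + 0i, N2)
  bands <- list()
  for (lev in seq_len(levels)) {
    l1 <- .filter_transfer(h, N1, lev) / sqrt(2)
    g1 <- .filter_transfer(g, N1, lev) / sqrt(2)
    l2 <- .filter_transfer(h, N2, lev) / sqrt(2)
    g2 <- .filter_transfer(g, N2, lev) / sqrt(2)
    bands[[length(bands) + 1]] <- outer(A1 * l1, A2 * g2)   # LH
    bands[[length(bands) + 1]] <- outer(A1 * g1, A2 * l2)   # HL
    bands[[length(bands) + 1]] <- outer(A1 * g1, A2 * g2)   # HH
    A1 <- A1 * l1
    A2 <- A2 * l2
  }
  bands[[length(bands) + 1]] <- outer(A1, A2)               # final LL
  bands
}

#' Shift-invariant wavelet tight frame
#'
#' Undecimated (stationary) separable 2-D wavelet transform with periodic
#' boundaries, normalized per level so the frame is Parseval-tight. The
#' redundancy is `3 * levels + 1`.
#'
#' @param shape integer vector `c(N1, N2)`; both divisible by `2^levels`.
#' @param wavelet_name one of `"haar"`, `"db4"`, `"db8"` (tap counts).
#' @param levels number of decomposition levels.
#' @return a [frame_operator].
#' @export
make_sidwt_frame <- function(shape, wavelet_name = "db4", levels = 3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, levels >= 1)
  if (any(shape %% 2^levels != 0)) {
    stop("shape must be divisible by 2^levels", call. = FALSE)
  }
  h <- .get_filter(wavelet_name)
  H <- .sidwt_transfers(shape, h, levels)
  N <- prod(shape)
  nb <- length(H)
  analysis_fn <- function(x) {
    X <- stats::fft(x)
    out <- complex(nb * N)
    for (k in seq_len(nb)) {
      out[((k - 1) * N + 1):(k * N)] <-
        as.vector(stats::fft(H[[k]] * X, inverse = TRUE) / N)
    }
    out
  }
  synthesis_fn <- function(a) {
    acc <- matrix(0 + 0i, shape[1], shape[2])
    for (k in seq_len(nb)) {
      ak <- matrix(a[((k - 1) * N + 1):(k * N)], shape[1], shape[2])
      acc <- acc + Conj(H[[k]]) * stats::fft(ak)
    }
    stats::fft(acc, inverse = TRUE) / N
  }
  frame <- new_frame_operator(
    name = sprintf("sidwt(%s, %d levels)", wavelet_name, levels),
    shape = shape, D = nb * N, is_orthogonal = FALSE,
    analysis_fn = analysis_fn, synthesis_fn = synthesis_fn,
    params = list(wavelet = wavelet_name, levels = levels)
  )
  .validate_tightness(frame)
}

# ---------------------------------------------------------------------------
# Orthogonal decimated wavelet (Mallat periodic filter bank).
# ---------------------------------------------------------------------------

# One decimated analysis step along columns of a matrix; returns list(lo, hi),
# each with half the rows. Periodic (cyclic) extension.
.dwt_step_cols <- function(v, h, g) {
  N <- nrow(v)
  half <- N / 2
  idx <- outer(2 * (seq_len(half) - 1), seq_along(h) - 1, `+`) %% N + 1
  lo <- matrix(0 + 0i, half, ncol(v))
  hi <- matrix(0 + 0i, half, ncol(v))
  for (m in seq_along(h)) {
    lo <- lo + h[m] * v[idx[, m], , drop = FALSE]
    hi <- hi + g[m] * v[idx[, m], , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# Adjoint (= inverse for orthonormal filters) of .dwt_step_cols.
.idwt_step_cols <- function(lo, hi, h, g) {
  half <- nrow(lo)
  N <- 2 * half
  idx <- outer(2 * (seq_len(half) - 1), seq_along(h) - 1, `+`) %% N + 1
  v <- matrix(0 + 0i, N, ncol(lo))
  for (m in seq_along(h)) {
    rows <- idx[, m]
    v[rows, ] <- v[rows, ] + h[m] * lo + g[m] * hi
  }
  v
}

.dwt2_level <- function(x, h, g) {
  cs <- .dwt_step_cols(x, h, g)
  rl <- .dwt_step_cols(t(cs$lo), h, g)
  rh <- .dwt_step_cols(t(cs$hi), h, g)
  # ll, lh (low rows / high cols), hl, hh
  list(ll = t(rl$lo), lh = t(rl$hi), hl = t(rh$lo), hh = t(rh$hi))
}

.idwt2_level <- function(ll, lh, hl, hh, h, g) {
  lo <- t(.idwt_step_cols(t(ll), t(lh), h, g))
  hi <- t(.idwt_step_cols(t(hl), t(hh), h, g))
  .idwt_step_cols(lo, hi, h, g)
}

#' Orthogonal wavelet frame
#'
#' Decimated separable 2-D orthogonal wavelet transform with periodic
#' boundaries. `D = N`, the analysis map is unitary, and the range
#' projection is the identity: the analysis, synthesis and balanced
#' reconstruction models coincide for this frame.
#'
#' @inheritParams make_sidwt_frame
#' @return a [frame_operator] with `is_orthogonal = TRUE`.
#' @export
make_orthogonal_dwt_frame <- function(shape, wavelet_name = "db4", levels = 3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2, levels >= 1)
  if (any(shape %% 2^levels != 0)) {
    stop("shape must be divisible by 2^levels", call. = FALSE)
  }
  h <- .get_filter(wavelet_name)
  if (any(shape / 2^levels < length(h))) {
    stop("shape too small for ", length(h), "-tap filter at ", levels,
         " levels", call. = FALSE)
  }
  g <- .qmf(h)
  N <- prod(shape)
  analysis_fn <- function(x) {
    out <- list()
    cur <- x
    for (lev in seq_len(levels)) {
      b <- .dwt2_level(cur, h, g)
      out[[length(out) + 1]] <- as.vector(b$lh)
      out[[length(out) + 1]] <- as.vector(b$hl)
      out[[length(out) + 1]] <- as.vector(b$hh)
      cur <- b$ll
    }
    out[[length(out) + 1]] <- as.vector(cur)
    unlist(out)
  }
  synthesis_fn <- function(a) {
    sizes <- t(vapply(seq_len(levels), function(l) shape / 2^l, numeric(2)))
    # peel subbands finest-first, rebuild coarsest-first
    offs <- 0L
    det <- vector("list", levels)
    for (lev in seq_len(levels)) {
      n <- prod(sizes[lev, ])
      det[[lev]] <- list(
        lh = matrix(a[offs + seq_len(n)], sizes[lev, 1], sizes[lev, 2]),
        hl = matrix(a[offs + n + seq_len(n)], sizes[lev, 1], sizes[lev, 2]),
        hh = matrix(a[offs + 2 * n + seq_len(n)], sizes[lev, 1], sizes[lev, 2])
      )
      offs <- offs + 3L * n
    }
    cur <- matrix(a[offs + seq_len(prod(sizes[levels, ]))],
                  sizes[levels, 1], sizes[levels, 2])
    for (lev in rev(seq_len(levels))) {
      cur <- .idwt2_level(cur, det[[lev]]$lh, det[[lev]]$hl, det[[lev]]$hh,
                          h, g)
    }
    cur
  }
  frame <- new_frame_operator(
    name = sprintf("dwt(%s, %d levels)", wavelet_name, levels),
    shape = shape, D = N, is_orthogonal = TRUE,
    analysis_fn = analysis_fn, synthesis_fn = synthesis_fn,
    params = list(wavelet = wavelet_name, levels = levels)
  )
  .validate_tightness(frame)
}

# ---------------------------------------------------------------------------
# Translation-invariant DCT: orthogonal block DCT over all cyclic patch
# shifts, rescaled by 1/patch_size so the stacked system is tight.
# ---------------------------------------------------------------------------

.dct_matrix <- function(p) {
  C <- sqrt(2 / p) * cos(pi * outer(seq_len(p) - 1, 2 * seq_len(p) - 1) /
                           (2 * p))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

.blockdct2 <- function(x, C) {
  p <- nrow(C)
  xr <- matrix(C %*% matrix(x, nrow = p), nrow(x), ncol(x))
  t(matrix(C %*% matrix(t(xr), nrow = p), ncol(x), nrow(x)))
}

.iblockdct2 <- function(x, C) {
  p <- nrow(C)
  xr <- matrix(crossprod(C, matrix(x, nrow = p)), nrow(x), ncol(x))
  t(matrix(crossprod(C, matrix(t(xr), nrow = p)), ncol(x), nrow(x)))
}

.circshift2 <- function(x, s1, s2) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[(seq_len(n1) - 1 + s1) %% n1 + 1, (seq_len(n2) - 1 + s2) %% n2 + 1,
    drop = FALSE]
}

#' Translation-invariant DCT tight frame
#'
#' Orthogonal 2-D DCT applied to a `patch_size`-square partition of the
#' image under all `patch_size^2` cyclic shifts, rescaled by
#' `1/patch_size` so the stacked transform is Parseval-tight (redundancy
#' `patch_size^2`). With `patch_size` equal to the image size the shift
#' set degenerates to the identity and the frame is the plain orthogonal
#' 2-D DCT with `D = N`.
#'
#' @param shape integer vector `c(N1, N2)`; both divisible by `patch_size`.
#' @param patch_size patch edge length in pixels.
#' @return a [frame_operator].
#' @export
make_tidct_frame <- function(shape, patch_size = 8) {
  shape <- as.integer(shape)
  p <- as.integer(patch_size)
  stopifnot(length(shape) == 2)
  if (p < 1 || p > min(shape)) stop("invalid patch size", call. = FALSE)
  if (any(shape %% p != 0)) {
    stop("patch_size must divide both image dimensions", call. = FALSE)
  }
  C <- .dct_matrix(p)
  single <- (p == shape[1] && p == shape[2])
  shifts <- if (single) {
    list(c(0L, 0L))
  } else {
    unlist(lapply(0:(p - 1), function(s1) lapply(0:(p - 1), function(s2) {
      c(s1, s2)
    })), recursive = FALSE)
  }
  scale <- if (single) 1 else 1 / p
  N <- prod(shape)
  ns <- length(shifts)
  analysis_fn <- function(x) {
    out <- complex(ns * N)
    for (k in seq_len(ns)) {
      s <- shifts[[k]]
      out[((k - 1) * N + 1):(k * N)] <-
        as.vector(.blockdct2(.circshift2(x, s[1], s[2]), C)) * scale
    }
    out
  }
  synthesis_fn <- function(a) {
    acc <- matrix(0 + 0i, shape[1], shape[2])
    for (k in seq_len(ns)) {
      s <- shifts[[k]]
      blk <- .iblockdct2(matrix(a[((k - 1) * N + 1):(k * N)],
                                shape[1], shape[2]), C)
      acc <- acc + .circshift2(blk, -s[1], -s[2]) * scale
    }
    acc
  }
  frame <- new_frame_operator(
    name = sprintf("tidct(patch %d)", p),
    shape = shape, D = ns * N, is_orthogonal = single,
    analysis_fn = analysis_fn, synthesis_fn = synthesis_fn,
    params = list(patch_size = p)
  )
  .validate_tightness(frame)
}

#' Build a frame from a configuration name
#'
#' Convenience dispatcher used by the experiment runners and the command
#' line: `"sidwt"`, `"dwt"` (orthogonal) or `"tidct"`.
#'
#' @param name frame family name.
#' @param shape image shape `c(N1, N2)`.
#' @param wavelet_name,levels passed to the wavelet constructors.
#' @param patch_size passed to [make_tidct_frame()].
#' @return a [frame_operator].
#' @export
make_frame <- function(name, shape, wavelet_name = "db4", levels = 3,
                       patch_size = 8) {
  switch(name,
    sidwt = make_sidwt_frame(shape, wavelet_name, levels),
    dwt = make_orthogonal_dwt_frame(shape, wavelet_name, levels),
    tidct = make_tidct_frame(shape, patch_size),
    stop("unknown frame '", name, "'", call. = FALSE)
  )
}
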