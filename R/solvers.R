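#' Solvers for the constrained balanced sparse model
#'
#' The balanced model reconstructs an image \eqn{\hat{x} = \Psi^*\hat\alpha}
#' from undersampled k-space data \eqn{y} by
#' \deqn{\min_\alpha \lambda\|\alpha\|_1 +
#'   \frac{\beta}{2}\|(I-\Psi\Psi^*)\alpha\|_2^2
#'   \quad \mathrm{s.t.}\quad \|y - UF\Psi^*\alpha\|_2^2 \le \sigma^2.}
#' The penalty weight \eqn{\beta \in [0, \infty]} measures the distance of
#' the coefficients from the range of \eqn{\Psi} and is reparameterized as
#' \eqn{\gamma = \rho/(\rho+\beta) \in [0,1]}: \eqn{\gamma = 0} is the
#' analysis model, \eqn{\gamma = 1} the synthesis model, values between
#' interpolate. All three solvers here expose \eqn{\gamma} as the
#' user-facing knob.
#'
#' `csalsa_b()` solves the constrained form by ADMM with an exact
#' closed-form coefficient update; `admm_b()` and `apg()` solve the
#' unconstrained relaxation with data-fidelity weight `delta_fid`.
#'
#' @name balanced_model
NULL

#' Solver configuration
#'
#' Bundles every tunable of the three solvers. Defaults follow the
#' parameter set used throughout the reference experiments: C-SALSA-B
#' runs with `lambda = 0.05`, `gamma = 0.5`, `rho = mu = delta_h =
#' delta_d = 1`; `lambda = 0.01` suits ADMM-B and `lambda = 0.005` APG.
#'
#' @param lambda l1 weight, > 0.
#' @param gamma balance parameter in \[0, 1\] (0 = analysis, 1 =
#'   synthesis). Ignored when `beta` is given.
#' @param beta optional off-range penalty weight (may be `Inf`); when
#'   supplied, `gamma` is derived as `rho / (rho + beta)`.
#' @param rho coefficient-splitting penalty, > 0.
#' @param mu measurement-splitting penalty of C-SALSA-B, > 0.
#' @param delta_h,delta_d multiplier step sizes, > 0.
#' @param sigma_sq constraint level \eqn{\sigma^2} for C-SALSA-B.
#' @param delta_fid data-fidelity weight \eqn{\delta} of the unconstrained
#'   baselines (ADMM-B, APG).
#' @param max_iter iteration cap.
#' @param tol relative-change stopping tolerance on the image iterate.
#' @param monotone use the monotone-restart APG variant (default) rather
#'   than plain momentum.
#' @param relax optional over-relaxation factor for ADMM-B in (0, 2\];
#'   1 disables relaxation.
#' @return a `solver_config` list.
#' @export
solver_config <- function(lambda = 0.05, gamma = 0.5, beta = NULL, rho = 1,
                          mu = 1, delta_h = 1, delta_d = 1, sigma_sq = 0,
                          delta_fid = 1, max_iter = 100, tol = 1e-5,
                          monotone = TRUE, relax = 1) {
  if (!is.null(beta)) gamma <- gamma_from_beta(beta, rho)
  stopifnot(lambda > 0 || lambda == 0, rho > 0, mu > 0, delta_h > 0,
            delta_d > 0, delta_fid > 0, sigma_sq >= 0, max_iter >= 1,
            tol >= 0, relax > 0, relax <= 2)
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  structure(
    list(lambda = lambda, gamma = gamma, rho = rho, mu = mu,
         delta_h = delta_h, delta_d = delta_d, sigma_sq = sigma_sq,
         delta_fid = delta_fid, max_iter = as.integer(max_iter), tol = tol,
         monotone = monotone, relax = relax),
    class = "solver_config"
  )
}

#' Balance parameter from the off-range penalty weight
#'
#' \eqn{\gamma = \rho / (\rho + \beta)}: maps \eqn{\beta = 0} to 1
#' (synthesis model) and \eqn{\beta = \infty} to 0 (analysis model).
#'
#' @param beta off-range penalty weight, \eqn{\ge 0}; `Inf` allowed.
#' @param rho splitting penalty, > 0.
#' @return gamma in \[0, 1\].
#' @export
gamma_from_beta <- function(beta, rho) {
  if (any(beta < 0) || any(rho <= 0)) {
    stop("beta must be >= 0 and rho > 0", call. = FALSE)
  }
  ifelse(is.infinite(beta), 0, rho / (rho + beta))
}

# Inverse map; only valid for gamma > 0 (gamma = 0 means beta = Inf).
.beta_from_gamma <- function(gamma, rho) {
  if (gamma == 0) Inf else rho * (1 - gamma) / gamma
}

#' Complex soft-thresholding
#'
#' The proximal operator of the l1 norm, applied entrywise by magnitude:
#' \eqn{\mathcal{T}_t(v) = \max(|v| - t, 0) \cdot v / |v|} (zero stays
#' zero). Real inputs reduce to the familiar
#' \eqn{\max(|v| - t, 0)\,\mathrm{sgn}(v)} shrinkage.
#'
#' @param v complex (or real) vector.
#' @param t threshold, \eqn{\ge 0}.
#' @return vector of the same length.
#' @export
soft_threshold <- function(v, t) {
  if (t < 0) stop("threshold must be nonnegative", call. = FALSE)
  if (t == 0) return(v)
  m <- Mod(v)
  w <- pmax(m - t, 0)
  scale <- ifelse(m > 0, w / m, 0)
  v * scale
}

#' Closed-form coefficient update
#'
#' Exact unique minimizer of the quadratic coefficient subproblem of the
#' augmented Lagrangian,
#' \deqn{\min_\alpha \frac{\beta}{2}\|(I-\Psi\Psi^*)\alpha\|^2 +
#'   \frac{\mu}{2}\|UF\Psi^*\alpha - y - h\|^2 +
#'   \frac{\rho}{2}\|\alpha - z - d\|^2,}
#' evaluated as
#' \deqn{\alpha^+ = \frac{\mu}{\mu+\rho}\Psi F^*U^*(y+h) + \gamma(z+d) +
#'   \Psi F^*\left[(1-\gamma)I - \frac{\mu}{\mu+\rho}U^*U\right]
#'   F\Psi^*(z+d).}
#' Exactness requires a Parseval-tight frame and a binary mask (so that
#' \eqn{U^*U} is a 0/1 diagonal in the unitary Fourier basis); the
#' formula is stable at both endpoints \eqn{\gamma = 0} (\eqn{\beta \to
#' \infty}) and \eqn{\gamma = 1} (\eqn{\beta = 0}).
#'
#' @param z,d complex coefficient vectors of length `frame$D`.
#' @param h complex measurement-domain multiplier of length `M` (0 for
#'   the unconstrained baselines).
#' @param kdata a [measure()] result.
#' @param frame a Parseval-tight [frame_operator].
#' @param mu,rho positive penalties.
#' @param gamma balance parameter in \[0, 1\].
#' @return updated complex coefficient vector.
#' @export
alpha_update <- function(z, d, h, kdata, frame, mu, rho, gamma) {
  mask <- kdata$mask
  q <- z + d
  cc <- mu / (mu + rho)
  m_nc <- .mask_nc(mask)
  Kq <- ft2(synthesis(q, frame))
  K <- cc * .embed_nc(kdata$samples + h, mask) +
    ((1 - gamma) - cc * m_nc) * Kq
  gamma * q + analysis(ift2(K), frame)
}

# ---------------------------------------------------------------------------
# Independent oracle: iterative linear solve of the subproblem's normal
# equations. Used in tests to certify the closed form; not used by solvers.
# ---------------------------------------------------------------------------

# Conjugate gradient for a Hermitian positive definite operator on complex
# vectors.
.cg_solve <- function(apply_A, b, tol = 1e-12, max_iter = 2000) {
  x <- b * 0
  r <- b
  p <- r
  rs <- Re(sum(Conj(r) * r))
  b_norm <- sqrt(Re(sum(Conj(b) * b)))
  if (b_norm == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- apply_A(p)
    a <- rs / Re(sum(Conj(p) * Ap))
    x <- x + a * p
    r <- r - a * Ap
    rs_new <- Re(sum(Conj(r) * r))
    if (sqrt(rs_new) / b_norm < tol) return(x)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  stop("conjugate gradient did not converge", call. = FALSE)
}

#' Iterative-solver oracle for the coefficient subproblem
#'
#' Solves the normal equations
#' \eqn{[\beta(I-\Psi\Psi^*) + \mu(UF\Psi^*)^*(UF\Psi^*) + \rho I]\alpha =
#' \mu(UF\Psi^*)^*(y+h) + \rho(z+d)} by conjugate gradient, independently
#' of the closed form in [alpha_update()]. For `gamma = 0`
#' (\eqn{\beta = \infty}) the constrained problem is solved on the range
#' of \eqn{\Psi} via its image-domain reduction. Intended for small
#' instances and testing.
#'
#' @inheritParams alpha_update
#' @param tol conjugate-gradient residual tolerance.
#' @return complex coefficient vector.
#' @export
subproblem_oracle <- function(z, d, h, kdata, frame, mu, rho, gamma,
                              tol = 1e-12) {
  mask <- kdata$mask
  m_nc <- .mask_nc(mask)
  q <- z + d
  rhs_img <- mu * ift2(.embed_nc(kdata$samples + h, mask))
  if (gamma == 0) {
    # alpha = Psi w with [mu F* U*U F + rho I] w = mu F*U*(y+h) + rho Psi* q
    apply_A <- function(wv) {
      w <- matrix(wv, mask$shape[1], mask$shape[2])
      as.vector(mu * ift2(m_nc * ft2(w)) + rho * w)
    }
    b <- as.vector(rhs_img + rho * synthesis(q, frame))
    w <- .cg_solve(apply_A, b, tol = tol)
    return(analysis(matrix(w, mask$shape[1], mask$shape[2]), frame))
  }
  beta <- .beta_from_gamma(gamma, rho)
  apply_A <- function(a) {
    pa <- range_projection(a, frame)
    w <- synthesis(a, frame)
    beta * (a - pa) +
      mu * analysis(ift2(m_nc * ft2(w)), frame) +
      rho * a
  }
  b <- analysis(rhs_img, frame) + rho * q
  .cg_solve(apply_A, b, tol = tol)
}

# ---------------------------------------------------------------------------
# Shared solver plumbing.
# ---------------------------------------------------------------------------

.relative_change <- function(x_hat, x_prev, solver, iter) {
  relch <- sqrt(sum(Mod(x_hat - x_prev)^2)) /
    max(sqrt(sum(Mod(x_prev)^2)), .Machine$double.eps)
  if (!is.finite(relch)) {
    stop(solver, " diverged at iteration ", iter,
         " (non-finite iterate); check lambda/rho/mu/delta settings",
         call. = FALSE)
  }
  relch
}

.check_finite_iterate <- function(a, solver, iter) {
  if (any(!is.finite(Re(a))) || any(!is.finite(Im(a)))) {
    stop(solver, " diverged at iteration ", iter,
         " (non-finite iterate); check lambda/rho/mu/delta settings",
         call. = FALSE)
  }
}

.objective_value <- function(a, z, frame, lambda, rho, gamma) {
  l1 <- lambda * sum(Mod(z))
  if (gamma == 0 || gamma == 1) return(l1)  # off-range penalty vanishes
  beta <- .beta_from_gamma(gamma, rho)
  off <- a - range_projection(a, frame)
  l1 + beta / 2 * sum(Mod(off)^2)
}

new_solver_result <- function(solver, image, coefficients, trace, config,
                              frame, converged) {
  structure(
    list(solver = solver, image = image, coefficients = coefficients,
         trace = trace, iterations_run = nrow(trace), config = config,
         frame_name = frame$name, converged = converged),
    class = "solver_result"
  )
}

#' @export
print.solver_result <- function(x, ...) {
  final_rlne <- x$trace$rlne[x$iterations_run]
  cat(sprintf("<solver_result: %s on %s, %d iterations%s%s>\n",
              x$solver, x$frame_name, x$iterations_run,
              if (x$converged) " (converged)" else " (iteration cap)",
              if (is.na(final_rlne)) "" else
                sprintf(", final RLNE %.4g", final_rlne)))
  invisible(x)
}

#' C-SALSA-B: constrained split augmented Lagrangian shrinkage
#'
#' ADMM on the constrained balanced model with splitting \eqn{z = \alpha}
#' and an exact measurement constraint handled by a second multiplier.
#' Each iteration performs the closed-form [alpha_update()], the
#' soft-threshold update \eqn{z_{n+1} = \mathcal{T}_{\lambda/\rho}
#' (\alpha_{n+1} - d_n)}, and the multiplier steps
#' \eqn{h_{n+1} = h_n - \delta_h(UF\Psi^*\alpha_{n+1} - y)},
#' \eqn{d_{n+1} = d_n - \delta_d(\alpha_{n+1} - z_{n+1})}.
#'
#' Initialization: \eqn{z_1 = \Psi} applied to the zero-filled
#' reconstruction, \eqn{d_1 = 0}, \eqn{h_1 = 0}. Stopping: relative
#' change of \eqn{\hat{x}} below `tol` and, when `sigma_sq > 0`, the
#' constraint value \eqn{\|y - UF\Psi^*\alpha\|^2 \le \sigma^2}; always
#' at `max_iter`.
#'
#' @param kdata undersampled measurements from [measure()].
#' @param frame a Parseval-tight [frame_operator].
#' @param config a [solver_config()].
#' @param x_true optional ground-truth image; when given, the per-iteration
#'   RLNE is recorded in the trace.
#' @return a `solver_result` with the reconstruction, final coefficients
#'   and per-iteration traces (objective, constraint value, RLNE).
#' @export
csalsa_b <- function(kdata, frame, config = solver_config(), x_true = NULL) {
  stopifnot(inherits(kdata, "kspace_data"), inherits(config, "solver_config"))
  cfg <- config
  z <- analysis(zero_fill_adjoint(kdata), frame)
  d <- z * 0
  h <- kdata$samples * 0
  x_prev <- NULL
  tr_obj <- tr_con <- tr_rlne <- numeric(cfg$max_iter)
  converged <- FALSE
  n_done <- cfg$max_iter
  for (n in seq_len(cfg$max_iter)) {
    a <- alpha_update(z, d, h, kdata, frame, cfg$mu, cfg$rho, cfg$gamma)
    .check_finite_iterate(a, "csalsa_b", n)
    z <- soft_threshold(a - d, cfg$lambda / cfg$rho)
    x_hat <- synthesis(a, frame)
    r <- .forward_masked(x_hat, kdata$mask) - kdata$samples
    h <- h - cfg$delta_h * r
    d <- d - cfg$delta_d * (a - z)
    tr_obj[n] <- .objective_value(a, z, frame, cfg$lambda, cfg$rho, cfg$gamma)
    tr_con[n] <- sum(Mod(r)^2)
    tr_rlne[n] <- if (is.null(x_true)) NA_real_ else rlne(x_hat, x_true)
    if (!is.null(x_prev)) {
      relch <- .relative_change(x_hat, x_prev, "csalsa_b", n)
      if (relch < cfg$tol &&
          (cfg$sigma_sq == 0 || tr_con[n] <= cfg$sigma_sq)) {
        converged <- TRUE
        n_done <- n
        break
      }
    }
    x_prev <- x_hat
  }
  trace <- tibble::tibble(iter = seq_len(n_done),
                          objective = tr_obj[seq_len(n_done)],
                          constraint = tr_con[seq_len(n_done)],
                          rlne = tr_rlne[seq_len(n_done)])
  new_solver_result("csalsa_b", x_hat, a, trace, cfg, frame, converged)
}

#' ADMM-B: ADMM on the unconstrained balanced objective
#'
#' Solves \eqn{\min_\alpha \lambda\|z\|_1 +
#' \frac{\beta}{2}\|(I-\Psi\Psi^*)\alpha\|^2 +
#' \frac{\delta}{2}\|y-UF\Psi^*\alpha\|^2} with the splitting
#' \eqn{z = \alpha}. Its coefficient subproblem is the same quadratic as
#' C-SALSA-B's with \eqn{(\mu, y+h)} replaced by \eqn{(\delta, y)}, so
#' the same closed form applies with no measurement multiplier. The
#' `relax` config field applies standard ADMM over-relaxation to the
#' splitting (1 = none).
#'
#' @inheritParams csalsa_b
#' @return a `solver_result`.
#' @export
admm_b <- function(kdata, frame, config = solver_config(lambda = 0.01),
                   x_true = NULL) {
  stopifnot(inherits(kdata, "kspace_data"), inherits(config, "solver_config"))
  cfg <- config
  z <- analysis(zero_fill_adjoint(kdata), frame)
  d <- z * 0
  h0 <- kdata$samples * 0
  x_prev <- NULL
  tr_obj <- tr_con <- tr_rlne <- numeric(cfg$max_iter)
  converged <- FALSE
  n_done <- cfg$max_iter
  for (n in seq_len(cfg$max_iter)) {
    a <- alpha_update(z, d, h0, kdata, frame, cfg$delta_fid, cfg$rho,
                      cfg$gamma)
    .check_finite_iterate(a, "admm_b", n)
    a_rel <- if (cfg$relax == 1) a else cfg$relax * a + (1 - cfg$relax) * z
    z <- soft_threshold(a_rel - d, cfg$lambda / cfg$rho)
    d <- d - cfg$delta_d * (a_rel - z)
    x_hat <- synthesis(a, frame)
    r <- .forward_masked(x_hat, kdata$mask) - kdata$samples
    tr_obj[n] <- .objective_value(a, z, frame, cfg$lambda, cfg$rho, cfg$gamma)
    tr_con[n] <- sum(Mod(r)^2)
    tr_rlne[n] <- if (is.null(x_true)) NA_real_ else rlne(x_hat, x_true)
    if (!is.null(x_prev)) {
      relch <- .relative_change(x_hat, x_prev, "solver", n)
      if (relch < cfg$tol) {
        converged <- TRUE
        n_done <- n
        break
      }
    }
    x_prev <- x_hat
  }
  trace <- tibble::tibble(iter = seq_len(n_done),
                          objective = tr_obj[seq_len(n_done)],
                          constraint = tr_con[seq_len(n_done)],
                          rlne = tr_rlne[seq_len(n_done)])
  new_solver_result("admm_b", x_hat, a, trace, cfg, frame, converged)
}

# Gradient of the smooth part of the unconstrained balanced objective:
# f(a) = beta/2 ||(I-P)a||^2 + delta/2 ||UF Psi* a - y||^2.
.apg_gradient <- function(a, kdata, frame, beta, delta) {
  r <- .forward_masked(synthesis(a, frame), kdata$mask) - kdata$samples
  beta * (a - range_projection(a, frame)) +
    delta * analysis(ift2(.embed_nc(r, kdata$mask)), frame)
}

.apg_smooth_value <- function(a, kdata, frame, beta, delta) {
  r <- .forward_masked(synthesis(a, frame), kdata$mask) - kdata$samples
  off <- a - range_projection(a, frame)
  beta / 2 * sum(Mod(off)^2) + delta / 2 * sum(Mod(r)^2)
}

#' Accelerated proximal gradient for the unconstrained balanced objective
#'
#' FISTA-type iteration on the same objective as [admm_b()]: gradient
#' step on the smooth part \eqn{f(\alpha) =
#' \frac{\beta}{2}\|(I-\Psi\Psi^*)\alpha\|^2 +
#' \frac{\delta}{2}\|y-UF\Psi^*\alpha\|^2} with step \eqn{1/L},
#' \eqn{L = \beta + \delta} (exact Lipschitz bound for a Parseval frame
#' and unitary DFT), soft-threshold prox with \eqn{\lambda/L}, and
#' Nesterov momentum \eqn{t_{k+1} = (1+\sqrt{1+4t_k^2})/2}. With
#' `config$monotone = TRUE` (default) momentum restarts whenever the
#' objective increases. Requires `gamma > 0` (finite \eqn{\beta}).
#'
#' @inheritParams csalsa_b
#' @return a `solver_result`.
#' @export
apg <- function(kdata, frame, config = solver_config(lambda = 0.005),
                x_true = NULL) {
  stopifnot(inherits(kdata, "kspace_data"), inherits(config, "solver_config"))
  cfg <- config
  if (cfg$gamma == 0) {
    stop("apg requires gamma > 0 (the analysis limit beta = Inf has no ",
         "finite gradient); use csalsa_b for gamma = 0", call. = FALSE)
  }
  beta <- .beta_from_gamma(cfg$gamma, cfg$rho)
  delta <- cfg$delta_fid
  L <- beta + delta
  a <- analysis(zero_fill_adjoint(kdata), frame)
  v <- a
  t_k <- 1
  obj_prev <- Inf
  x_prev <- NULL
  tr_obj <- tr_con <- tr_rlne <- numeric(cfg$max_iter)
  converged <- FALSE
  n_done <- cfg$max_iter
  for (n in seq_len(cfg$max_iter)) {
    g <- .apg_gradient(v, kdata, frame, beta, delta)
    a_new <- soft_threshold(v - g / L, cfg$lambda / L)
    .check_finite_iterate(a_new, "apg", n)
    obj <- cfg$lambda * sum(Mod(a_new)) +
      .apg_smooth_value(a_new, kdata, frame, beta, delta)
    if (cfg$monotone && obj > obj_prev) {
      # restart momentum from the previous iterate
      t_k <- 1
      v <- a
      g <- .apg_gradient(v, kdata, frame, beta, delta)
      a_new <- soft_threshold(v - g / L, cfg$lambda / L)
      obj <- cfg$lambda * sum(Mod(a_new)) +
        .apg_smooth_value(a_new, kdata, frame, beta, delta)
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    v <- a_new + ((t_k - 1) / t_next) * (a_new - a)
    a <- a_new
    t_k <- t_next
    obj_prev <- obj
    x_hat <- synthesis(a, frame)
    r <- .forward_masked(x_hat, kdata$mask) - kdata$samples
    tr_obj[n] <- .objective_value(a, a, frame, cfg$lambda, cfg$rho, cfg$gamma)
    tr_con[n] <- sum(Mod(r)^2)
    tr_rlne[n] <- if (is.null(x_true)) NA_real_ else rlne(x_hat, x_true)
    if (!is.null(x_prev)) {
      relch <- .relative_change(x_hat, x_prev, "solver", n)
      if (relch < cfg$tol) {
        converged <- TRUE
        n_done <- n
        break
      }
    }
    x_prev <- x_hat
  }
  trace <- tibble::tibble(iter = seq_len(n_done),
                          objective = tr_obj[seq_len(n_done)],
                          constraint = tr_con[seq_len(n_done)],
                          rlne = tr_rlne[seq_len(n_done)])
  new_solver_result("apg", x_hat, a, trace, cfg, frame, converged)
}
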