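#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solver result
#'
#' Returns the per-iteration trace as a tibble with columns `iter`,
#' `objective` (\eqn{\lambda\|z\|_1} plus the off-range penalty),
#' `constraint` (\eqn{\|y-UF\Psi^*\alpha\|_2^2}) and `rlne` (`NA` when no
#' ground truth was supplied), plus the solver name.
#'
#' @param x a `solver_result`.
#' @param ... unused.
#' @return a tibble with one row per iteration.
#' @export
tidy.solver_result <- function(x, ...) {
  dplyr::mutate(x$trace, solver = x$solver, .before = 1)
}

#' One-row summary of a solver result
#'
#' @param x a `solver_result`.
#' @param ... unused.
#' @return a tibble with solver, frame, gamma, iterations, convergence
#'   flag, final objective/constraint/RLNE.
#' @export
glance.solver_result <- function(x, ...) {
  n <- x$iterations_run
  tibble::tibble(
    solver = x$solver, frame = x$frame_name, gamma = x$config$gamma,
    iterations = n, converged = x$converged,
    objective = x$trace$objective[n], constraint = x$trace$constraint[n],
    rlne = x$trace$rlne[n]
  )
}

#' Plot solver convergence traces
#'
#' Log-scale per-iteration panels for the objective, the constraint value
#' and (when available) the RLNE.
#'
#' @param object a `solver_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.solver_result <- function(object, ...) {
  df <- tidy.solver_result(object)
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = sprintf("%s on %s", object$solver,
                                  object$frame_name)) +
    ggplot2::theme_minimal()
}

# Minimal long-format reshape of a trace tibble (avoids a tidyr dependency
# for one pivot).
tidyr_pivot <- function(df) {
  quantities <- c("objective", "constraint", "rlne")
  quantities <- quantities[vapply(quantities, function(q) {
    !all(is.na(df[[q]]))
  }, logical(1))]
  dplyr::bind_rows(lapply(quantities, function(q) {
    tibble::tibble(iter = df$iter, quantity = q, value = df[[q]])
  }))
}
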