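#' Experiment runners
#'
#' High-level drivers reproducing the study designs on synthetic data:
#' single reconstructions, balancing-parameter sweeps, sampling-ratio
#' sweeps and solver convergence comparisons. All return tibbles so
#' results chain directly into dplyr/ggplot2 pipelines; companions with a
#' `plot_` prefix draw the standard figures. The command-line front end
#' (`inst/cli/balancedcs`) wraps these functions.
#'
#' @name experiments
NULL

.solver_fn <- function(name) {
  switch(name,
    csalsa_b = csalsa_b, admm_b = admm_b, apg = apg,
    stop("unknown solver '", name, "'", call. = FALSE)
  )
}

#' Reconstruct one fixture with one solver
#'
#' Runs the chosen solver and, when `out_dir` is given, writes the
#' reconstructed magnitude PNG, the complex result container, the trace
#' CSV (columns iter, objective, constraint, rlne) and a manifest with
#' the full configuration.
#'
#' @param fixture a [make_fixture()] result (or anything with `image`
#'   and `kdata`).
#' @param frame a [frame_operator].
#' @param solver `"csalsa_b"`, `"admm_b"` or `"apg"`.
#' @param config a [solver_config()].
#' @param out_dir optional output directory.
#' @return the `solver_result` (invisibly when writing files).
#' @export
reconstruct_experiment <- function(fixture, frame, solver = "csalsa_b",
                                   config = solver_config(),
                                   out_dir = NULL) {
  res <- .solver_fn(solver)(fixture$kdata, frame, config,
                            x_true = fixture$image)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_magnitude_png(res$image, file.path(out_dir, "reconstruction.png"))
    write_complex_image(res$image, file.path(out_dir, "reconstruction.json"))
    utils::write.csv(res$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    manifest <- list(solver = solver, frame = frame$name,
                     config = unclass(config), fixture = fixture$spec,
                     final_rlne = res$trace$rlne[res$iterations_run],
                     iterations = res$iterations_run,
                     r_version = as.character(getRversion()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    return(invisible(res))
  }
  res
}

#' Balancing-parameter sweep
#'
#' Runs C-SALSA-B over a grid of \eqn{\gamma} values for each supplied
#' frame on one fixture, recording the final RLNE and iteration count.
#' For tight (redundant) frames the error typically grows as \eqn{\gamma}
#' moves from the analysis end (0) to the synthesis end (1); for an
#' orthogonal frame the curve is flat.
#'
#' @param fixture a [make_fixture()] result.
#' @param frames named list of [frame_operator]s.
#' @param gammas numeric grid in \[0, 1\].
#' @param config base [solver_config()]; its `gamma` is overridden.
#' @return tibble with columns `frame`, `gamma`, `rlne`, `iterations`.
#' @export
sweep_gamma <- function(fixture, frames,
                        gammas = seq(0, 1, by = 0.1),
                        config = solver_config()) {
  stopifnot(is.list(frames), !is.null(names(frames)))
  purrr::map_dfr(names(frames), function(fname) {
    purrr::map_dfr(gammas, function(g) {
      cfg <- config
      cfg$gamma <- g
      res <- csalsa_b(fixture$kdata, frames[[fname]], cfg,
                      x_true = fixture$image)
      tibble::tibble(frame = fname, gamma = g,
                     rlne = res$trace$rlne[res$iterations_run],
                     iterations = res$iterations_run)
    })
  })
}

#' Sampling-ratio sweep
#'
#' For each sampling fraction and each model (analysis \eqn{\gamma=0},
#' balanced \eqn{\gamma=0.5}, synthesis \eqn{\gamma=1}), regenerates the
#' mask and measurements and records the final RLNE; optionally repeated
#' over several mask seeds so medians smooth out mask-draw variability.
#'
#' @param kind,shape,phase_model phantom parameters, see [make_phantom()].
#' @param fractions sampling fractions to test.
#' @param gammas model grid (named by convention 0 / 0.5 / 1).
#' @param seeds mask seeds; one sweep per seed.
#' @param frame a [frame_operator] matching `shape`.
#' @param config base [solver_config()].
#' @param noise_sigma measurement noise level.
#' @return tibble with columns `fraction`, `gamma`, `model`, `seed`,
#'   `rlne`.
#' @export
sweep_sampling <- function(frame, kind = "shepp_logan", shape = c(64, 64),
                           fractions = seq(0.15, 1, by = 0.05),
                           gammas = c(0, 0.5, 1), seeds = 1:5,
                           config = solver_config(), noise_sigma = 0,
                           phase_model = "zero") {
  model_name <- function(g) {
    if (g == 0) "analysis" else if (g == 1) "synthesis" else "balanced"
  }
  purrr::map_dfr(seeds, function(s) {
    purrr::map_dfr(fractions, function(fr) {
      fx <- make_fixture(kind = kind, shape = shape, sampling_fraction = fr,
                         noise_sigma = noise_sigma, seed = s,
                         phase_model = phase_model)
      purrr::map_dfr(gammas, function(g) {
        cfg <- config
        cfg$gamma <- g
        res <- csalsa_b(fx$kdata, frame, cfg, x_true = fx$image)
        tibble::tibble(fraction = fr, gamma = g, model = model_name(g),
                       seed = s, rlne = res$trace$rlne[res$iterations_run])
      })
    })
  })
}

#' Compare solver convergence
#'
#' Runs C-SALSA-B, ADMM-B and APG on the same fixture with their default
#' parameter sets, collects per-iteration RLNE traces, and summarizes
#' iterations-to-threshold, where the threshold is `threshold_factor`
#' times the best final RLNE among the solvers.
#'
#' @param fixture a [make_fixture()] result.
#' @param frame a [frame_operator].
#' @param configs named list of [solver_config()]s for `csalsa_b`,
#'   `admm_b`, `apg`; defaults follow the reference parameter table.
#' @param threshold_factor multiplier on the best final RLNE.
#' @return list with `traces` (tibble: solver, iter, rlne, objective,
#'   constraint) and `summary` (tibble: solver, iterations_to_threshold,
#'   final_rlne, threshold).
#' @export
compare_algorithms <- function(fixture, frame,
                               configs = list(
                                 csalsa_b = solver_config(lambda = 0.05),
                                 admm_b = solver_config(lambda = 0.01),
                                 apg = solver_config(lambda = 0.005)
                               ),
                               threshold_factor = 1.05) {
  results <- purrr::imap(configs, function(cfg, name) {
    .solver_fn(name)(fixture$kdata, frame, cfg, x_true = fixture$image)
  })
  traces <- purrr::imap_dfr(results, function(res, name) {
    dplyr::mutate(res$trace, solver = name, .before = 1)
  })
  finals <- vapply(results, function(r) r$trace$rlne[r$iterations_run],
                   numeric(1))
  threshold <- threshold_factor * min(finals)
  summary <- purrr::imap_dfr(results, function(res, name) {
    hit <- which(res$trace$rlne <= threshold)
    tibble::tibble(
      solver = name,
      iterations_to_threshold = if (length(hit)) min(hit) else NA_integer_,
      final_rlne = res$trace$rlne[res$iterations_run],
      threshold = threshold
    )
  })
  list(traces = traces, summary = summary)
}

#' Plot a balancing-parameter sweep
#'
#' @param df output of [sweep_gamma()].
#' @return a ggplot object.
#' @export
plot_gamma_sweep <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$rlne,
                                   color = .data$frame)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(gamma), y = "RLNE",
                  title = "Reconstruction error vs balancing parameter") +
    ggplot2::theme_minimal()
}

#' Plot a sampling-ratio sweep
#'
#' @param df output of [sweep_sampling()]; medians are taken over seeds.
#' @return a ggplot object.
#' @export
plot_sampling_sweep <- function(df) {
  med <- dplyr::summarise(dplyr::group_by(df, .data$fraction, .data$model),
                          rlne = stats::median(.data$rlne), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(x = .data$fraction, y = .data$rlne,
                                    color = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "sampling fraction", y = "median RLNE",
                  title = "Reconstruction error vs sampling ratio") +
    ggplot2::theme_minimal()
}

#' Plot solver convergence comparison
#'
#' @param comparison output of [compare_algorithms()].
#' @return a ggplot object.
#' @export
plot_convergence <- function(comparison) {
  ggplot2::ggplot(comparison$traces,
                  ggplot2::aes(x = .data$iter, y = .data$rlne,
                               color = .data$solver)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "RLNE",
                  title = "Convergence of the three solvers") +
    ggplot2::theme_minimal()
}
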