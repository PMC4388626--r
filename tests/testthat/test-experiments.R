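# Experiment runners, tidy/broom surface, and the command-line front end.

small_fixture <- function() {
  cached("fx32", function() make_fixture(shape = c(32, 32), seed = 9))
}

small_frame <- function() {
  cached("fr32", function() make_sidwt_frame(c(32, 32), "db4", 2))
}

test_that("reconstruct_experiment runs each solver and writes artifacts", {
  fx <- small_fixture()
  fr <- small_frame()
  for (s in c("csalsa_b", "admm_b", "apg")) {
    res <- reconstruct_experiment(fx, fr, solver = s,
                                  config = solver_config(max_iter = 10))
    expect_s3_class(res, "solver_result")
    expect_identical(nrow(res$trace), res$iterations_run)
  }
  dir <- withr::local_tempdir()
  reconstruct_experiment(fx, fr, config = solver_config(max_iter = 10),
                         out_dir = dir)
  expect_true(file.exists(file.path(dir, "reconstruction.png")))
  expect_true(file.exists(file.path(dir, "reconstruction.json")))
  expect_true(file.exists(file.path(dir, "trace.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$iterations, 10)
  tr <- utils::read.csv(file.path(dir, "trace.csv"))
  expect_named(tr, c("iter", "objective", "constraint", "rlne"))
})

test_that("gamma sweep covers the grid and is flat for orthogonal frames", {
  fx <- small_fixture()
  frames <- list(dwt = make_orthogonal_dwt_frame(c(32, 32), "db4", 2))
  df <- sweep_gamma(fx, frames, gammas = c(0, 0.5, 1),
                    config = solver_config(max_iter = 30))
  expect_setequal(df$gamma, c(0, 0.5, 1))
  expect_lt(max(df$rlne) - min(df$rlne), 1e-3)
})

test_that("sampling sweep output is tidy and full sampling is exact", {
  fr <- small_frame()
  df <- sweep_sampling(fr, shape = c(32, 32), fractions = c(0.4, 1.0),
                       gammas = c(0, 0.5, 1), seeds = 1,
                       config = solver_config(lambda = 0.01, max_iter = 150,
                                              tol = 1e-6))
  expect_named(df, c("fraction", "gamma", "model", "seed", "rlne"))
  expect_setequal(df$model, c("analysis", "balanced", "synthesis"))
  full <- df[df$fraction == 1, ]
  expect_true(all(full$rlne < 1e-3))
  # error can only grow when fewer samples are taken
  for (m in unique(df$model)) {
    sub <- df[df$model == m, ]
    expect_gte(sub$rlne[sub$fraction == 0.4], sub$rlne[sub$fraction == 1])
  }
})

test_that("algorithm comparison is deterministic with a sane summary", {
  fx <- small_fixture()
  fr <- small_frame()
  cfgs <- list(csalsa_b = solver_config(lambda = 0.05, max_iter = 40),
               admm_b = solver_config(lambda = 0.01, max_iter = 40),
               apg = solver_config(lambda = 0.005, max_iter = 40))
  c1 <- compare_algorithms(fx, fr, configs = cfgs)
  c2 <- compare_algorithms(fx, fr, configs = cfgs)
  expect_identical(c1$traces, c2$traces)
  expect_setequal(c1$summary$solver, c("csalsa_b", "admm_b", "apg"))
  expect_equal(c1$summary$threshold[1], 1.05 * min(c1$summary$final_rlne))
})

test_that("tidy, glance and autoplot expose the result surface", {
  fx <- small_fixture()
  res <- csalsa_b(fx$kdata, small_frame(), solver_config(max_iter = 10),
                  x_true = fx$image)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("solver", "iter", "objective", "constraint", "rlne"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$rlne, td$rlne[nrow(td)])
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_convergence(compare_algorithms(
    fx, small_frame(),
    configs = list(csalsa_b = solver_config(max_iter = 5)))), "ggplot")
})

test_that("command-line front end reconstructs a phantom end to end", {
  cli <- system.file("cli", "balancedcs", package = "balancedcs")
  expect_true(nzchar(cli) && file.exists(cli))
  dir <- withr::local_tempdir()
  out <- system2("Rscript",
                 c(cli, "reconstruct", "--size", "32", "--fraction", "0.5",
                   "--solver", "csalsa_b", "--max-iter", "5",
                   "--out-dir", dir),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "trace.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
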