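two_curve_ensemble <- function(W, grid = seq(1, 0, by = -0.25)) {
  dplyr::bind_rows(
    tibble::tibble(run = 1, lambda = grid, work = 0 * (1 - grid)),
    tibble::tibble(run = 2, lambda = grid, work = W * (1 - grid)))
}

test_that("identical work curves give back the work curve as the PMF", {
  grid <- seq(1, 0, by = -0.1)
  w <- 12 * (1 - grid)^2
  curves <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(run = i, lambda = grid, work = w)
  }))
  pmf <- jarzynski_pmf(curves, work_unit = "kcal/mol")
  expect_equal(pmf$phi, w, tolerance = 1e-10)
  expect_equal(pmf$sigma, rep(0, length(grid)))
  expect_equal(pmf$sd_kcal, rep(0, length(grid)))
})

test_that("Gaussian work ensembles recover the cumulant closed form", {
  kT <- kT_kcal(298)
  curves <- gaussian_work_ensemble(mu = 10, sd = 1, n = 1e4, seed = 21)
  pmf <- jarzynski_pmf(curves, temperature = 298, work_unit = "kcal/mol")
  terminal <- curves$work[curves$lambda == 0]
  expected <- 10 - 1 / (2 * kT)
  # delta-method standard error of the exponential-average estimate
  b <- exp(-(terminal - min(terminal)) / kT)
  se <- kT * stats::sd(b) / (sqrt(length(b)) * mean(b))
  expect_lt(abs(pmf$phi[nrow(pmf)] - expected), 3 * se)
  # sigma matches (beta/2) * population SD
  sd_pop <- stats::sd(terminal) * sqrt((length(terminal) - 1) / length(terminal))
  expect_equal(pmf$sigma[nrow(pmf)], sd_pop / (2 * kT), tolerance = 1e-10)
})

test_that("two-curve ensembles match the explicit two-term closed forms", {
  kT <- kT_kcal(298)
  W <- 3
  pmf <- jarzynski_pmf(two_curve_ensemble(W), work_unit = "kcal/mol")
  phi_exact <- -kT * log((1 + exp(-W / kT)) / 2)
  expect_equal(pmf$phi[pmf$lambda == 0], phi_exact, tolerance = 1e-12)
  # sigma closed form: population SD of {0, W} is W/2
  sig <- work_std(two_curve_ensemble(W), work_unit = "kcal/mol")
  expect_equal(sig$sigma[sig$lambda == 0], (W / 2) / (2 * kT), tolerance = 1e-12)
  expect_equal(sig$sd_kcal[sig$lambda == 0], W / 2, tolerance = 1e-12)
})

test_that("Jensen bound holds pointwise with equality only for identical curves", {
  withr::with_seed(31, {
    grid <- seq(1, 0, by = -0.2)
    curves <- dplyr::bind_rows(lapply(1:8, function(i) {
      tibble::tibble(run = i, lambda = grid,
                     work = cumsum(c(0, abs(rnorm(5, 2)))))
    }))
  })
  pmf <- jarzynski_pmf(curves, work_unit = "kcal/mol")
  expect_true(all(pmf$phi <= pmf$mean_work + 1e-10))
  # strict inequality where curves differ
  expect_true(all((pmf$phi < pmf$mean_work - 1e-10)[-1]))
  # duplicating a curve keeps Phi inside [min work, mean work]
  dup <- dplyr::bind_rows(curves, dplyr::mutate(curves[curves$run == 1, ], run = 9))
  pmf2 <- jarzynski_pmf(dup, work_unit = "kcal/mol")
  mins <- dplyr::summarise(dplyr::group_by(dup, .data$lambda),
                           lo = min(work), hi = mean(work))
  mins <- dplyr::arrange(mins, dplyr::desc(lambda))
  expect_true(all(pmf2$phi >= mins$lo - 1e-10))
  expect_true(all(pmf2$phi <= mins$hi + 1e-10))
})

test_that("estimator accuracy improves with ensemble size on Gaussian work", {
  kT <- kT_kcal(298)
  expected <- 10 - 1 / (2 * kT)
  err <- vapply(c(1e2, 1e4), function(n) {
    curves <- gaussian_work_ensemble(10, 1, n, seed = 1234)
    pmf <- jarzynski_pmf(curves, work_unit = "kcal/mol")
    abs(pmf$phi[nrow(pmf)] - expected)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("delta_w is the profile range and delta_delta_w its symmetric difference", {
  grid <- seq(1, 0, by = -0.25)
  mono <- jarzynski_pmf(
    tibble::tibble(run = rep(1:2, each = 5), lambda = rep(grid, 2),
                   work = rep(12.5 * (1 - grid), 2)),
    work_unit = "kcal/mol")
  expect_equal(delta_w(mono), 12.5)
  # interior maximum wins over the endpoint
  hump <- jarzynski_pmf(
    tibble::tibble(run = rep(1:2, each = 5), lambda = rep(grid, 2),
                   work = rep(c(0, 10, 15, 8, 5), 2)),
    work_unit = "kcal/mol")
  expect_equal(delta_w(hump), 15)
  flat <- jarzynski_pmf(
    tibble::tibble(run = rep(1:2, each = 5), lambda = rep(grid, 2), work = 0),
    work_unit = "kcal/mol")
  expect_equal(delta_w(flat), 0)
  # the sequence-specificity measure: |dW_A - dW_B|, symmetric, zero on self
  a <- jarzynski_pmf(tibble::tibble(run = rep(1:2, each = 5), lambda = rep(grid, 2),
                                    work = rep(23.27 * (1 - grid), 2)),
                     work_unit = "kcal/mol")
  b <- jarzynski_pmf(tibble::tibble(run = rep(1:2, each = 5), lambda = rep(grid, 2),
                                    work = rep(15.05 * (1 - grid), 2)),
                     work_unit = "kcal/mol")
  expect_equal(delta_delta_w(a, b), 8.22, tolerance = 1e-12)
  expect_equal(delta_delta_w(b, a), delta_delta_w(a, b))
  expect_equal(delta_delta_w(a, a), 0)
})

test_that("kJ/mol input and reduced-kT input are converted consistently", {
  grid <- seq(1, 0, by = -0.5)
  curves_kj <- tibble::tibble(run = rep(1:2, each = 3), lambda = rep(grid, 2),
                              work = rep(4.184 * c(0, 5, 10), 2))
  pmf <- jarzynski_pmf(curves_kj, work_unit = "kJ/mol")
  expect_equal(delta_w(pmf), 10)  # kcal/mol out
  pmf_red <- jarzynski_pmf(
    tibble::tibble(run = rep(1:2, each = 3), lambda = rep(grid, 2),
                   work = rep(c(0, 1, 2), 2)), work_unit = "kT")
  expect_equal(delta_w(pmf_red), 2)
  expect_error(jarzynski_pmf(curves_kj, work_unit = "eV"), "unknown work unit")
})

test_that("single-curve ensembles degrade to the work curve with a warning", {
  one <- tibble::tibble(run = 1, lambda = seq(1, 0, by = -0.5), work = c(0, 2, 5))
  expect_warning(pmf <- jarzynski_pmf(one, work_unit = "kcal/mol"),
                 class = "pullpmf_single_curve")
  expect_equal(pmf$phi, c(0, 2, 5))
})

test_that("work-curve files are validated, gauge-fixed and grid-aligned", {
  td <- withr::local_tempdir()
  grid_a <- seq(5, 0, length.out = 11)   # center counts
  grid_b <- seq(5, 0, length.out = 21)   # denser grid
  f1 <- file.path(td, "a.colvar")
  f2 <- file.path(td, "b.colvar")
  write_colvar(tibble::tibble(time_ps = 0:10, cv = grid_a, center = grid_a,
                              work = seq(0, 10, length.out = 11)), f1)
  write_colvar(tibble::tibble(time_ps = 0:20, cv = grid_b, center = grid_b,
                              work = seq(0, 8, length.out = 21)), f2)
  curves <- read_work_curves(c(f1, f2), lambda_map(5, 0))
  expect_equal(dplyr::n_distinct(curves$run), 2)
  # both runs now live on the 21-point grid
  expect_equal(nrow(curves), 42)
  expect_equal(unique(table(curves$lambda)), 2L)
  # linear interpolation preserved the linear work curve exactly
  a <- curves[curves$run == 1, ]
  expect_equal(a$work, 10 * (1 - a$lambda), tolerance = 1e-9)
  # nonzero starting work is shifted with a warning
  f3 <- file.path(td, "c.colvar")
  write_colvar(tibble::tibble(time_ps = 0:10, cv = grid_a, center = grid_a,
                              work = seq(2, 12, length.out = 11)), f3)
  expect_warning(shifted <- read_work_curves(f3, lambda_map(5, 0)),
                 class = "pullpmf_work_gauge")
  expect_equal(shifted$work[1], 0)
  # ascending center = wrong pull direction
  f4 <- file.path(td, "d.colvar")
  write_colvar(tibble::tibble(time_ps = 0:10, cv = rev(grid_a),
                              center = rev(grid_a),
                              work = seq(0, 10, length.out = 11)), f4)
  expect_error(read_work_curves(f4, lambda_map(5, 0)), "not descending")
  # empty file
  f5 <- file.path(td, "e.colvar")
  writeLines("#! FIELDS time cv center work", f5)
  expect_error(read_work_curves(f5, lambda_map(5, 0)), "no data rows")
})

test_that("tidy and glance expose profile summaries", {
  curves <- gaussian_work_ensemble(5, 0.5, 50, seed = 2)
  pmf <- jarzynski_pmf(curves, work_unit = "kcal/mol")
  td <- tidy(pmf)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("lambda", "phi", "sigma") %in% names(td)))
  gl <- glance(pmf)
  expect_equal(gl$delta_w, delta_w(pmf))
  expect_equal(gl$n_runs, 50)
  expect_equal(gl$unit, "kcal/mol")
})
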