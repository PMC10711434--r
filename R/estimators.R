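work_to_kcal <- function(w, unit) {
  switch(unit,
         "kJ/mol" = kj_to_kcal(w),
         "kcal/mol" = w,
         rlang::abort(sprintf("unknown work unit '%s'", unit)))
}

#' Read an ensemble of work-lambda curves
#'
#' Reads COLVAR-style tables (see [read_colvar()]), one file per steered
#' run, into a single long work-curve tibble. Files carrying a `work`
#' column use it directly; otherwise work is recomputed from the `cv` /
#' `center` series via [accumulate_work()] (the two routes agree to
#' discretization error). All runs are linearly interpolated onto the
#' densest lambda grid found, so the ensemble shares one axis. A curve
#' whose first work value is non-zero is shifted to zero with a warning
#' (the work origin is a gauge choice).
#'
#' @param paths COLVAR file paths, one per run.
#' @param lambda_map A [lambda_map()] converting restraint-center contact
#'   counts to lambda.
#' @param schedule Optional [steering_schedule()]; required when any file
#'   lacks a `work` column. Its lambda map overrides `lambda_map`.
#' @return A tibble with columns `run`, `lambda` (descending per run),
#'   `work`, plus any per-group contact or RMSD columns present in the
#'   files, of class `work_ensemble`.
#' @export
read_work_curves <- function(paths, lambda_map = NULL, schedule = NULL) {
  if (!is.null(schedule)) {
    stopifnot(is_steering_schedule(schedule))
    lambda_map <- schedule$lambda_map
  }
  if (!is_lambda_map(lambda_map)) {
    rlang::abort("supply a `lambda_map` (or a schedule)")
  }
  curves <- purrr::imap(paths, function(p, i) {
    dat <- read_colvar(p)
    if (!"center" %in% names(dat)) {
      rlang::abort(sprintf("%s: no `center` column", p))
    }
    if ("work" %in% names(dat)) {
      cur <- tibble::tibble(
        lambda = lambda_of_contacts(dat$center, lambda_map),
        work = dat$work)
      extra <- setdiff(names(dat), c("time_ps", "cv", "center", "work"))
      cur <- dplyr::bind_cols(cur, dat[extra])
    } else {
      if (is.null(schedule)) {
        rlang::abort(sprintf("%s: no `work` column and no schedule to recompute it", p))
      }
      cur <- accumulate_work(dat, schedule)
      cur$time_ps <- NULL
    }
    if (any(diff(cur$lambda) > 1e-12)) {
      rlang::abort(sprintf("%s: lambda grid is not descending (inconsistent pull direction)", p))
    }
    if (abs(cur$work[1]) > 1e-9) {
      rlang::warn(sprintf("%s: work[0] = %g, shifting curve to start at 0",
                          p, cur$work[1]),
                  class = "pullpmf_work_gauge")
      cur$work <- cur$work - cur$work[1]
    }
    cur$run <- i
    cur
  })
  grids <- purrr::map(curves, "lambda")
  dense <- grids[[which.max(lengths(grids))]]
  curves <- purrr::map(curves, function(cur) {
    if (isTRUE(all.equal(cur$lambda, dense))) return(cur)
    num <- setdiff(names(cur), c("lambda", "run"))
    res <- purrr::map(num, function(col) {
      stats::approx(cur$lambda, cur[[col]], xout = dense, rule = 2)$y
    })
    names(res) <- num
    dplyr::bind_cols(tibble::tibble(lambda = dense), tibble::as_tibble(res),
                     tibble::tibble(run = cur$run[1]))
  })
  out <- dplyr::bind_rows(curves)
  class(out) <- c("work_ensemble", class(out))
  out
}

#' Jarzynski potential of mean force from a work ensemble
#'
#' Pointwise over the shared lambda grid, the free-energy profile is the
#' exponential average of the run work values,
#' `Phi(lambda) = -(1/beta) * (logsumexp(-beta w_i) - log N)`, evaluated
#' with log-sum-exp stabilization, and offset so the fully inserted end
#' (first grid point, lambda = 1) is zero. Two error fields accompany it:
#' `sigma`, the dimensionless (beta/2)-weighted population standard
#' deviation of the work (see [work_std()]), and `sd_kcal`, the plain
#' population SD in kcal/mol.
#'
#' @param curves Long work-curve tibble with columns `run`, `lambda`,
#'   `work` ([read_work_curves()], [gaussian_work_ensemble()], or
#'   [toy_work_curves()]).
#' @param temperature Temperature in K entering beta.
#' @param work_unit Unit of the `work` column: `"kJ/mol"` (engine
#'   convention, default), `"kcal/mol"`, or `"kT"` (reduced toy-simulator
#'   units, in which case `beta = 1` and output stays in kT).
#' @return A tibble of class `pmf_profile` with columns `lambda`, `phi`,
#'   `sigma`, `sd_kcal`, `mean_work`, `n_runs`; free energies in kcal/mol
#'   (or kT in reduced mode). Attributes `temperature` and `unit`.
#' @examples
#' curves <- gaussian_work_ensemble(mu = 10, sd = 1, n = 1000, seed = 7)
#' pmf <- jarzynski_pmf(curves, work_unit = "kcal/mol")
#' delta_w(pmf)
#' @export
jarzynski_pmf <- function(curves, temperature = 298, work_unit = "kJ/mol") {
  curves <- tibble::as_tibble(curves)
  stopifnot(all(c("run", "lambda", "work") %in% names(curves)),
            temperature > 0)
  n_runs <- dplyr::n_distinct(curves$run)
  if (n_runs < 2) {
    rlang::warn("single work curve: Phi equals the work curve itself (no ensemble averaging)",
                class = "pullpmf_single_curve")
  }
  if (work_unit == "kT") {
    kT <- 1
    w <- curves$work
    unit <- "kT"
  } else {
    kT <- kT_kcal(temperature)
    w <- work_to_kcal(curves$work, work_unit)
    unit <- "kcal/mol"
  }
  dat <- tibble::tibble(lambda = curves$lambda, w = w)
  prof <- dplyr::summarise(
    dplyr::group_by(dat, .data$lambda),
    phi = -kT * (logsumexp(-.data$w / kT) - log(dplyr::n())),
    sd_kcal = stats::sd(.data$w) * sqrt((dplyr::n() - 1) / dplyr::n()),
    mean_work = mean(.data$w),
    n_runs = dplyr::n(),
    .groups = "drop")
  prof$sd_kcal[is.na(prof$sd_kcal)] <- 0  # single run
  prof <- dplyr::arrange(prof, dplyr::desc(.data$lambda))
  prof$phi <- prof$phi - prof$phi[1]
  prof$mean_work <- prof$mean_work - prof$mean_work[1]
  prof$sigma <- prof$sd_kcal / (2 * kT)
  prof <- prof[c("lambda", "phi", "sigma", "sd_kcal", "mean_work", "n_runs")]
  attr(prof, "temperature") <- temperature
  attr(prof, "unit") <- unit
  class(prof) <- c("pmf_profile", class(prof))
  prof
}

#' Work standard deviation profile
#'
#' The ensemble error band as printed on free-energy plots: the population
#' standard deviation of the work over runs at each lambda, both in its
#' dimensionless (beta/2)-weighted form `sigma = (beta/2) sqrt(<w^2> -
#' <w>^2)` and as the plain SD in energy units.
#'
#' @inheritParams jarzynski_pmf
#' @return A tibble with columns `lambda`, `sigma` (dimensionless),
#'   `sd_kcal`.
#' @export
work_std <- function(curves, temperature = 298, work_unit = "kJ/mol") {
  prof <- jarzynski_pmf(curves, temperature, work_unit)
  tibble::as_tibble(prof)[c("lambda", "sigma", "sd_kcal")]
}

#' Free-energy range of a profile and its sequence difference
#'
#' `delta_w()` is the range `max(Phi) - min(Phi)` over the lambda grid, the
#' estimate of the dissociation free-energy difference between the bound
#' complex (profile minimum) and the dissociated state (profile maximum).
#' `delta_delta_w()` is the absolute difference of two systems' ranges -
#' the sequence-specificity measure - and is symmetric in its arguments.
#'
#' @param pmf,pmf_a,pmf_b [jarzynski_pmf()] profiles.
#' @return A single number in the profiles' energy unit.
#' @export
delta_w <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  max(pmf$phi) - min(pmf$phi)
}

#' @rdname delta_w
#' @export
delta_delta_w <- function(pmf_a, pmf_b) {
  abs(delta_w(pmf_a) - delta_w(pmf_b))
}

#' @export
tidy.pmf_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.pmf_profile <- function(x, ...) {
  tibble::tibble(
    delta_w = delta_w(x),
    lambda_min = x$lambda[which.min(x$phi)],
    lambda_max = x$lambda[which.max(x$phi)],
    n_runs = max(x$n_runs),
    temperature = attr(x, "temperature"),
    unit = attr(x, "unit")
  )
}

#' @rdname jarzynski_pmf
#' @param pmf A `pmf_profile`.
#' @param path Output TSV path.
#' @export
write_pmf_tsv <- function(pmf, path) {
  utils::write.table(tibble::as_tibble(pmf), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
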