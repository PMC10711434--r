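#' Steering schedule
#'
#' Defines one constant-velocity pull: the harmonic restraint center moves
#' linearly in time from the contact count mapped to lambda = 1 down to the
#' count mapped to lambda = 0 (fully inserted -> backbone-bound direction).
#'
#' @param lambda_map A [lambda_map()].
#' @param duration_ns Pull duration in ns; positive.
#' @param force_constant Restraint stiffness in kJ/mol per squared contact
#'   count (the collective variable is dimensionless).
#' @param n_runs Number of independent pulls in the ensemble.
#' @return An object of class `steering_schedule`.
#' @examples
#' steering_schedule(lambda_map(108, 65), duration_ns = 100,
#'                   force_constant = 500, n_runs = 20)
#' @export
steering_schedule <- function(lambda_map, duration_ns, force_constant,
                              n_runs = 20) {
  if (!is_lambda_map(lambda_map)) rlang::abort("`lambda_map` must be a lambda_map")
  stopifnot(is.numeric(duration_ns), duration_ns > 0,
            is.numeric(force_constant), force_constant > 0,
            n_runs >= 1)
  structure(list(lambda_map = lambda_map, duration_ns = duration_ns,
                 force_constant = force_constant, n_runs = as.integer(n_runs)),
            class = "steering_schedule")
}

is_steering_schedule <- function(x) inherits(x, "steering_schedule")

#' @export
print.steering_schedule <- function(x, ...) {
  cat(sprintf(
    "<steering_schedule> %g -> %g contacts over %g ns, k = %g kJ/mol (per contact^2), %d runs\n",
    x$lambda_map$c_start, x$lambda_map$c_end, x$duration_ns,
    x$force_constant, x$n_runs))
  invisible(x)
}

#' Select steering start frames from equilibrium contact series
#'
#' Draws a uniform random sample (without replacement) of frames whose
#' per-donor contact counts fall simultaneously inside every stated window,
#' emulating the selection of independent bound-state configurations from
#' equilibrium trajectories. The H-NS study conditions use windows
#' `Q112: 10.25 +/- 0.125` and `R114: 23 +/- 0.25` and n = 20.
#'
#' @param contacts Tibble from [contact_series()] (or any tibble with a
#'   `frame` column plus one column per windowed group).
#' @param windows Named list group -> `c(center, halfwidth)`.
#' @param n Number of frames to draw.
#' @param seed Integer seed; the draw is reproducible under it.
#' @return Integer vector of `frame` values, sorted.
#' @export
select_start_frames <- function(contacts, windows, n, seed = 1L) {
  contacts <- tibble::as_tibble(contacts)
  if (length(windows) == 0) rlang::abort("`windows` must be non-empty")
  if (!"frame" %in% names(contacts)) rlang::abort("`contacts` needs a frame column")
  ok <- rep(TRUE, nrow(contacts))
  for (g in names(windows)) {
    if (!g %in% names(contacts)) {
      rlang::abort(sprintf("window group '%s' is not a column of `contacts`", g))
    }
    w <- windows[[g]]
    ok <- ok & abs(contacts[[g]] - w[1]) <= w[2]
  }
  qualifying <- contacts$frame[ok]
  if (length(qualifying) < n) {
    rlang::abort(sprintf(
      "only %d frames satisfy all windows; %d requested",
      length(qualifying), n))
  }
  sel <- withr::with_seed(seed, sample(qualifying, n, replace = FALSE))
  sort(sel)
}

fmt_plumed_num <- function(x) {
  if (is.integer(x) || x == round(x)) {
    if (is.integer(x)) return(sprintf("%d", x))
    return(sprintf("%.1f", x))
  }
  format(x, digits = 15, scientific = FALSE)
}

#' Emit a steering-engine input file
#'
#' Renders the contact-map collective variable (rational switching function
#' with the spec's exact parameter literals), the linearly moving harmonic
#' restraint from `c_start` to `c_end`, and a fixed-stride output of
#' time/CV/center/work columns in the PLUMED input dialect. Output is
#' deterministic: identical inputs give byte-identical text.
#'
#' @param spec A [contact_map_spec()] whose pairs carry `donor_eleno` /
#'   `acceptor_eleno` atom serials (see [build_contact_map()]).
#' @param schedule A [steering_schedule()].
#' @param dialect Only `"plumed"` is supported.
#' @param dt_fs Engine time step in fs (converts `duration_ns` to steps).
#' @param stride Output stride in steps.
#' @param colvar_file Name of the table the engine will write.
#' @return A character vector of input lines; write with [writeLines()] or
#'   [write_steering_input()].
#' @export
emit_steering_input <- function(spec, schedule, dialect = "plumed",
                                dt_fs = 2, stride = 1000,
                                colvar_file = "COLVAR") {
  stopifnot(is_contact_map_spec(spec), is_steering_schedule(schedule))
  if (!identical(dialect, "plumed")) {
    rlang::abort(sprintf("unsupported steering dialect '%s'", dialect))
  }
  if (!all(c("donor_eleno", "acceptor_eleno") %in% names(spec$pairs))) {
    rlang::abort("spec pairs need donor_eleno/acceptor_eleno serials; rebuild with `structure =`")
  }
  sw <- spec$switching
  n_steps <- round(schedule$duration_ns * 1e6 / dt_fs)
  p <- spec$pairs
  atoms <- sprintf("  ATOMS%d=%d,%d SWITCH%d={RATIONAL R_0=%s D_0=%s NN=%s MM=%s}",
                   seq_len(nrow(p)), p$donor_eleno, p$acceptor_eleno,
                   seq_len(nrow(p)),
                   fmt_plumed_num(sw$r0), fmt_plumed_num(sw$d0),
                   fmt_plumed_num(sw$nn), fmt_plumed_num(sw$mm))
  c(
    "# pullpmf steering input (dialect: plumed v2)",
    "UNITS LENGTH=nm ENERGY=kj/mol",
    "cmap: CONTACTMAP ...",
    atoms,
    "  SUM",
    "... CONTACTMAP",
    sprintf("steer: MOVINGRESTRAINT ARG=cmap STEP0=0 AT0=%s KAPPA0=%s STEP1=%d AT1=%s KAPPA1=%s",
            fmt_plumed_num(schedule$lambda_map$c_start),
            fmt_plumed_num(schedule$force_constant),
            n_steps,
            fmt_plumed_num(schedule$lambda_map$c_end),
            fmt_plumed_num(schedule$force_constant)),
    sprintf("PRINT ARG=cmap,steer.cmap_cntr,steer.work STRIDE=%d FILE=%s",
            as.integer(stride), colvar_file)
  )
}

#' @rdname emit_steering_input
#' @param path Output path.
#' @param ... Passed to `emit_steering_input()`.
#' @export
write_steering_input <- function(spec, schedule, path, ...) {
  writeLines(emit_steering_input(spec, schedule, ...), path)
  invisible(path)
}

#' Accumulate restraint work from a CV time series
#'
#' Post-hoc work accumulation for a moving harmonic restraint: the work done
#' on the system up to time `t_k` is the discrete sum
#' `w(t_k) = sum_{j<=k} k_f (c_ref(t_j) - C(t_j)) * dc_ref(t_j)`, with
#' `dc_ref(t_j) = c_ref(t_j) - c_ref(t_{j-1})` and `w(0) = 0`. The curve is
#' re-indexed on the lambda grid of the restraint center, so all runs of an
#' ensemble share a common lambda axis by construction.
#'
#' @param cv A tibble with columns `time_ps`, `cv` (instantaneous contact
#'   count) and `center` (restraint center); extra columns (per-group
#'   contacts, `rmsd_nm`, ...) are carried through.
#' @param schedule A [steering_schedule()]; supplies the force constant and
#'   the lambda map.
#' @param monotone Require the restraint center to be non-increasing (the
#'   fully-inserted -> backbone direction)? Default `TRUE`.
#' @return A tibble (one run's work curve) with columns `lambda`, `work`
#'   (same energy unit as `force_constant` per contact^2, i.e. kJ/mol for
#'   engine data) plus carried-through columns.
#' @export
accumulate_work <- function(cv, schedule, monotone = TRUE) {
  stopifnot(is_steering_schedule(schedule))
  cv <- tibble::as_tibble(cv)
  need <- c("time_ps", "cv", "center")
  if (!all(need %in% names(cv))) {
    rlang::abort("`cv` needs columns time_ps, cv, center")
  }
  if (nrow(cv) < 2) rlang::abort("CV series too short to accumulate work")
  if (any(diff(cv$time_ps) <= 0)) rlang::abort("times must increase strictly")
  dc <- c(0, diff(cv$center))
  if (monotone && any(dc > 1e-9)) {
    rlang::abort("restraint center increases but the schedule direction requires non-increasing center")
  }
  w <- cumsum(schedule$force_constant * (cv$center - cv$cv) * dc)
  extra <- setdiff(names(cv), c("cv", "center"))
  out <- tibble::tibble(
    lambda = lambda_of_contacts(cv$center, schedule$lambda_map),
    work = w
  )
  dplyr::bind_cols(out, cv[extra])
}

#' Read and write COLVAR-style tables
#'
#' Whitespace-delimited tables with a `#! FIELDS time cv center ...` header
#' line, the format both steering engines and the toy simulator emit. The
#' `work` column is optional; when absent it is recomputed from the series
#' via [accumulate_work()] by downstream readers.
#'
#' @param path File path.
#' @return `read_colvar()`: a tibble whose columns are the declared fields
#'   (time column renamed `time_ps`).
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  head <- readLines(path, n = 100)
  if (length(head) == 0) rlang::abort(sprintf("%s: empty COLVAR file", path))
  fl <- grep("^#!\\s*FIELDS", head, value = TRUE)
  if (length(fl) == 0) {
    rlang::abort(sprintf("%s: missing '#! FIELDS' header", path))
  }
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fl[1])), "\\s+")[[1]]
  dat <- utils::read.table(path, comment.char = "#", col.names = fields,
                           colClasses = "numeric")
  if (nrow(dat) == 0) rlang::abort(sprintf("%s: no data rows", path))
  if (anyNA(dat)) rlang::abort(sprintf("%s: non-numeric or missing values", path))
  out <- tibble::as_tibble(dat)
  if ("time" %in% names(out)) names(out)[names(out) == "time"] <- "time_ps"
  out
}

#' @rdname read_colvar
#' @param df Tibble of numeric columns; a `time_ps` column is written as
#'   `time`.
#' @param header Extra `#`-prefixed header lines (provenance: seeds,
#'   parameters) written above the FIELDS line.
#' @export
write_colvar <- function(df, path, header = character()) {
  df <- tibble::as_tibble(df)
  nm <- names(df)
  nm[nm == "time_ps"] <- "time"
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste("#! FIELDS", paste(nm, collapse = " ")), con)
  utils::write.table(df, con, col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
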