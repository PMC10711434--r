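#' Classify dissociation pathways from per-donor contact series
#'
#' Labels each steered run by the order in which the binding motif leaves
#' the groove. At the first time the total contact count crosses
#' `total_threshold` from above, the glutamine per-donor count `C_Q` is
#' read off (linear interpolation between the bracketing samples): a run is
#' `R-G-Q` (arginine detaches first) when `C_Q < q_threshold` and `Q-G-R`
#' (glutamine first) when `C_Q > q_threshold`. A value exactly at the
#' threshold is labeled `R-G-Q` and flagged in the `tie` column. Recrossing
#' series are classified at the first crossing. The rule is invariant to
#' uniform time-resampling of the series.
#'
#' @param curves A tibble with columns `run`, a total-contact column and a
#'   per-donor column, ordered in time within each run (any monotone index
#'   column - `time_ps`, `lambda` - defines the order they appear in).
#' @param q_group Name of the per-donor contact column read at the
#'   crossing (default `"Q112"`).
#' @param total_col Name of the total-contact column (default `"total"`).
#' @param total_threshold Total contact count defining the measurement
#'   point (default 30).
#' @param q_threshold Decision threshold on the per-donor count (default 5).
#' @return A tibble with one row per run: `run`, `label` (`"R-G-Q"` or
#'   `"Q-G-R"`), `c_q` (interpolated per-donor count at the crossing),
#'   `tie` (logical).
#' @export
classify_pathway <- function(curves, q_group = "Q112", total_col = "total",
                             total_threshold = 30, q_threshold = 5) {
  curves <- tibble::as_tibble(curves)
  for (col in c("run", q_group, total_col)) {
    if (!col %in% names(curves)) {
      rlang::abort(sprintf("column '%s' missing from `curves`", col))
    }
  }
  out <- dplyr::group_modify(dplyr::group_by(curves, .data$run), function(g, key) {
    tot <- g[[total_col]]
    cq <- g[[q_group]]
    if (tot[1] < total_threshold) {
      rlang::abort(sprintf(
        "run %s starts below the total threshold %g; series must cross it from above",
        key$run, total_threshold))
    }
    # first index k with tot[k] >= thr > tot[k+1]
    below <- which(tot < total_threshold)
    if (length(below) == 0) {
      rlang::abort(sprintf(
        "run %s never crosses total contact threshold %g", key$run, total_threshold))
    }
    k <- below[1] - 1L
    f <- (tot[k] - total_threshold) / (tot[k] - tot[k + 1])
    c_q <- cq[k] + f * (cq[k + 1] - cq[k])
    tie <- abs(c_q - q_threshold) < 1e-12
    label <- if (c_q < q_threshold || tie) "R-G-Q" else "Q-G-R"
    tibble::tibble(label = label, c_q = c_q, tie = tie)
  })
  dplyr::ungroup(out)
}

#' Correlate per-run maximum work with maximum DNA deformation
#'
#' For each run, takes the maximum work and the maximum RMSD of the DNA
#' over the pull, and reports the Pearson product-moment correlation over
#' runs - the diagnostic that high-work runs coincide with large DNA
#' deformation. With zero variance in either coordinate the correlation is
#' undefined and reported as `NA`.
#'
#' @param curves A tibble with columns `run`, `work` and an RMSD column.
#' @param rmsd_col Name of the RMSD column (default `"rmsd_nm"`).
#' @return An object of class `work_rmsd_cor`: use `tidy()` for the paired
#'   per-run maxima table and `glance()` for the correlation summary.
#' @export
correlate_max_work_rmsd <- function(curves, rmsd_col = "rmsd_nm") {
  curves <- tibble::as_tibble(curves)
  for (col in c("run", "work", rmsd_col)) {
    if (!col %in% names(curves)) {
      rlang::abort(sprintf("column '%s' missing from `curves`", col))
    }
  }
  maxima <- dplyr::summarise(
    dplyr::group_by(curves, .data$run),
    max_work = max(.data$work),
    max_rmsd = max(.data[[rmsd_col]]),
    .groups = "drop")
  if (nrow(maxima) < 3) rlang::abort("need at least 3 runs to correlate")
  r <- if (stats::sd(maxima$max_work) == 0 || stats::sd(maxima$max_rmsd) == 0) {
    NA_real_
  } else {
    stats::cor(maxima$max_work, maxima$max_rmsd)
  }
  structure(list(maxima = maxima, pearson_r = r, n_runs = nrow(maxima)),
            class = "work_rmsd_cor")
}

#' @export
print.work_rmsd_cor <- function(x, ...) {
  cat(sprintf("<work_rmsd_cor> %d runs, Pearson r = %s\n", x$n_runs,
              ifelse(is.na(x$pearson_r), "undefined (zero variance)",
                     sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' @export
tidy.work_rmsd_cor <- function(x, ...) x$maxima

#' @export
glance.work_rmsd_cor <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, n_runs = x$n_runs)
}
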