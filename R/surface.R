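#' Boltzmann-weighted 2D work surface over two per-donor coordinates
#'
#' Projects all (x, y, work) samples of an ensemble - typically the Q112
#' and R114 per-donor contact counts of every stored frame of every run -
#' onto a regular 2D grid (100 x 100 bins by default). Each occupied bin
#' holds the Boltzmann-weighted mean work of its samples,
#' `z = sum(w_k e^{-beta w_k}) / sum(e^{-beta w_k})`, evaluated with
#' log-sum-exp stabilization so low-work (mechanistically dominant) samples
#' control the surface. Empty bins are assigned a fill value strictly above
#' the maximum observed work (1.05 x max by default), so unexplored regions
#' read as high-work background.
#'
#' @param curves Long work-curve tibble with columns `work` plus the two
#'   coordinate columns named by `x_group` and `y_group` (in kcal/mol or as
#'   set by `work_unit`).
#' @param x_group,y_group Column names of the two per-donor contact
#'   coordinates (e.g. `"Q112"`, `"R114"`).
#' @param bins Number of bins per axis.
#' @param temperature Temperature in K entering beta.
#' @param work_unit `"kJ/mol"`, `"kcal/mol"` or `"kT"` (reduced).
#' @param fill_factor Multiplier on the maximum observed work for the
#'   empty-bin fill. When the maximum work is not positive the fill falls
#'   back to `max + (fill_factor - 1) * (|max| + 1)` so it stays strictly
#'   above the maximum.
#' @return A tibble of class `surface2d` with columns `xbin`, `ybin`,
#'   `x_mid`, `y_mid`, `z` (kcal/mol or kT), `n_samples` (0 for filled
#'   bins), covering all `bins^2` cells. Attributes: `x_edges`, `y_edges`,
#'   `fill`, `x_group`, `y_group`, `unit`.
#' @export
boltzmann_surface_2d <- function(curves, x_group, y_group, bins = 100,
                                 temperature = 298, work_unit = "kJ/mol",
                                 fill_factor = 1.05) {
  curves <- tibble::as_tibble(curves)
  for (g in c(x_group, y_group)) {
    if (!g %in% names(curves)) {
      rlang::abort(sprintf("coordinate group '%s' is not a column of `curves`", g))
    }
  }
  stopifnot("work" %in% names(curves), bins >= 2, fill_factor > 1)
  if (work_unit == "kT") {
    kT <- 1
    w <- curves$work
  } else {
    kT <- kT_kcal(temperature)
    w <- work_to_kcal(curves$work, work_unit)
  }
  x <- curves[[x_group]]
  y <- curves[[y_group]]
  xe <- seq(min(x), max(x), length.out = bins + 1)
  ye <- seq(min(y), max(y), length.out = bins + 1)
  xi <- pmin(findInterval(x, xe, rightmost.closed = TRUE), bins)
  yi <- pmin(findInterval(y, ye, rightmost.closed = TRUE), bins)
  max_w <- max(w)
  fill <- if (max_w > 0) max_w * fill_factor else
    max_w + (fill_factor - 1) * (abs(max_w) + 1)
  dat <- tibble::tibble(xbin = xi, ybin = yi, w = w)
  occ <- dplyr::summarise(
    dplyr::group_by(dat, .data$xbin, .data$ybin),
    z = {
      lw <- -.data$w / kT
      m <- max(lw)
      sum(.data$w * exp(lw - m)) / sum(exp(lw - m))
    },
    n_samples = dplyr::n(),
    .groups = "drop")
  grid <- tidyr::expand_grid(xbin = seq_len(bins), ybin = seq_len(bins))
  out <- dplyr::left_join(grid, occ, by = c("xbin", "ybin"))
  out$n_samples[is.na(out$n_samples)] <- 0L
  out$z[out$n_samples == 0] <- fill
  out$x_mid <- (xe[out$xbin] + xe[out$xbin + 1]) / 2
  out$y_mid <- (ye[out$ybin] + ye[out$ybin + 1]) / 2
  out <- out[c("xbin", "ybin", "x_mid", "y_mid", "z", "n_samples")]
  attr(out, "x_edges") <- xe
  attr(out, "y_edges") <- ye
  attr(out, "fill") <- fill
  attr(out, "x_group") <- x_group
  attr(out, "y_group") <- y_group
  attr(out, "unit") <- if (work_unit == "kT") "kT" else "kcal/mol"
  class(out) <- c("surface2d", class(out))
  out
}

#' @export
glance.surface2d <- function(x, ...) {
  tibble::tibble(
    bins = length(attr(x, "x_edges")) - 1,
    occupied = sum(x$n_samples > 0),
    samples = sum(x$n_samples),
    fill = attr(x, "fill"),
    z_min = min(x$z)
  )
}

#' @rdname boltzmann_surface_2d
#' @param surface A `surface2d`.
#' @param path Output TSV path (bin indices, midpoints, z, counts; edges in
#'   `#` header lines).
#' @export
write_surface_tsv <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# x_edges:", paste(signif(attr(surface, "x_edges"), 10), collapse = " ")),
    paste("# y_edges:", paste(signif(attr(surface, "y_edges"), 10), collapse = " ")),
    paste("# fill:", attr(surface, "fill"))
  ), con)
  suppressWarnings(utils::write.table(
    tibble::as_tibble(surface), con, sep = "\t",
    quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Optional polynomial smoothing of an occupied surface
#'
#' Cosmetic post-process: fits a bivariate polynomial (total degree
#' `degree`) to the occupied bins by least squares and returns the surface
#' with a `z_smooth` column. The binned construction remains authoritative;
#' smoothing is off by default everywhere.
#'
#' @param surface A [boltzmann_surface_2d()] result.
#' @param degree Total polynomial degree.
#' @return The surface tibble with an added `z_smooth` column (filled bins
#'   keep the fill value).
#' @export
smooth_surface <- function(surface, degree = 3) {
  occ <- surface[surface$n_samples > 0, ]
  fit <- stats::lm(z ~ stats::poly(x_mid, y_mid, degree = degree, raw = TRUE),
                   data = occ)
  surface$z_smooth <- surface$z
  surface$z_smooth[surface$n_samples > 0] <- stats::fitted(fit)
  surface
}
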