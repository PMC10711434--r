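#' Rational switching function parameters
#'
#' Parameters of the rational switching function that turns a donor-acceptor
#' distance into a smooth contact weight in (0, 1]. Two parameter sets matter
#' in practice: the descriptive set `r0 = 0.4, d0 = 0.25, nn = 2, mm = 4`
#' (counts hydrogen-bond-distance contacts as 1 and contacts at 0.7 nm as
#' 0.5) and the steering set `r0 = 3.0, d0 = 0.3, nn = 1, mm = 12`, whose
#' decay is close to linear so every contact is displaced at a constant rate
#' during pulling.
#'
#' @param r0 Decay length in nm; must be positive.
#' @param d0 Offset in nm below which the weight is exactly 1; non-negative.
#' @param nn,mm Positive integer exponents with `mm > nn`, guaranteeing decay
#'   to zero at large distance.
#' @return An object of class `switching_params`.
#' @seealso [switching_value()], [linearity_score()]
#' @examples
#' switching_params(0.4, 0.25, 2, 4)
#' steering_switching() # the near-linear pulling set
#' @export
switching_params <- function(r0, d0, nn, mm) {
  stopifnot(
    is.numeric(r0), length(r0) == 1, is.finite(r0), r0 > 0,
    is.numeric(d0), length(d0) == 1, is.finite(d0), d0 >= 0,
    length(nn) == 1, length(mm) == 1
  )
  nn <- as.integer(nn)
  mm <- as.integer(mm)
  if (is.na(nn) || is.na(mm) || nn < 1 || mm <= nn) {
    rlang::abort("switching exponents must satisfy mm > nn >= 1")
  }
  structure(list(r0 = r0, d0 = d0, nn = nn, mm = mm),
            class = "switching_params")
}

#' @rdname switching_params
#' @export
contact_switching <- function() switching_params(0.4, 0.25, 2, 4)

#' @rdname switching_params
#' @export
steering_switching <- function() switching_params(3.0, 0.3, 1, 12)

#' @export
print.switching_params <- function(x, ...) {
  cat(sprintf(
    "<switching_params> r0 = %g nm, d0 = %g nm, nn = %d, mm = %d\n",
    x$r0, x$d0, x$nn, x$mm))
  invisible(x)
}

is_switching_params <- function(x) inherits(x, "switching_params")

#' Contact weight of a donor-acceptor distance
#'
#' Evaluates the rational switching function: 1 for `r < d0`, otherwise
#' `(1 - x^nn) / (1 - x^mm)` with `x = (r - d0)/r0`. The removable 0/0
#' singularity at `x = 1` is replaced by its analytic limit `nn/mm` within
#' `|x - 1| < 1e-6`, avoiding catastrophic cancellation. The function is
#' continuous and non-increasing in `r`; with `mm > nn` it decays to 0.
#'
#' @param r Distance(s) in nm; non-negative and finite.
#' @param params A [switching_params()] object.
#' @return Contact weight(s) in (0, 1], same length as `r`.
#' @examples
#' p <- contact_switching()
#' switching_value(0.20, p) # hydrogen-bond distance -> 1
#' switching_value(0.70, p) # ~0.44
#' @export
switching_value <- function(r, params) {
  if (!is_switching_params(params)) {
    rlang::abort("`params` must be a switching_params object")
  }
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0)) {
    rlang::abort("`r` must be finite non-negative distances in nm")
  }
  x <- (r - params$d0) / params$r0
  out <- numeric(length(r))
  inner <- x < 0
  at_one <- !inner & abs(x - 1) < 1e-6
  rest <- !inner & !at_one
  out[inner] <- 1
  out[at_one] <- params$nn / params$mm
  if (any(rest)) {
    xr <- x[rest]
    out[rest] <- (1 - xr^params$nn) / (1 - xr^params$mm)
  }
  out
}

#' Near-linearity of a switching parameter set
#'
#' Coefficient of determination (R^2) of the switching function, sampled on
#' a uniform grid over `[r_lo, r_hi]`, against its least-squares straight
#' line. Used to verify that a steering parameter set decays near-linearly,
#' so the moving restraint displaces each contact at an approximately
#' constant rate.
#'
#' @param params A [switching_params()] object.
#' @param r_lo,r_hi Range in nm, `r_lo < r_hi`.
#' @param n Number of grid points (at least 100).
#' @return R^2 in `[0, 1]`.
#' @examples
#' linearity_score(steering_switching(), 0.3, 3.0) # >= 0.98
#' @export
linearity_score <- function(params, r_lo, r_hi, n = 201) {
  stopifnot(is.numeric(r_lo), is.numeric(r_hi), r_lo < r_hi, n >= 100)
  r <- seq(r_lo, r_hi, length.out = n)
  y <- switching_value(r, params)
  fit <- stats::lm(y ~ r)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
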