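#' Steered overdamped Langevin toy simulator
#'
#' Ground truth for the whole analysis pipeline: a scalar coordinate in a
#' model potential, dragged by a harmonic trap whose center moves linearly
#' from `x0` to `x1`, integrated with the Euler-Maruyama overdamped update
#' `x <- x - dt * dV/dx / gamma + sqrt(2 kT dt / gamma) * eta`. Work is
#' accumulated with the same discrete rule as [accumulate_work()], so toy
#' output and engine output are interchangeable. Everything is in reduced
#' units (`kT = 1` by default); convert with [toy_work_curves()] when
#' feeding kcal/mol-based estimators, or use `work_unit = "kT"` directly.
#'
#' @param potential `"flat"`, `"harmonic"` or `"double_well"`.
#' @param kappa Harmonic stiffness (reduced units).
#' @param barrier,well_sep Double-well barrier height and half separation:
#'   `V = barrier * ((x/well_sep)^2 - 1)^2`.
#' @param friction Friction gamma.
#' @param kT Thermal energy (reduced).
#' @param dt Time step; must satisfy `dt * (kappa + k_trap) / gamma < 0.1`.
#' @param n_steps Steps per run.
#' @param seed Integer seed; trajectories are bit-reproducible under it.
#' @return `langevin_spec()`: object of class `langevin_spec`.
#' @export
langevin_spec <- function(potential = c("flat", "harmonic", "double_well"),
                          kappa = 1, barrier = 2, well_sep = 1,
                          friction = 1, kT = 1, dt = 1e-3,
                          n_steps = 1000L, seed = 1L) {
  potential <- match.arg(potential)
  stopifnot(friction > 0, kT > 0, dt > 0, n_steps >= 2)
  structure(list(potential = potential, kappa = kappa, barrier = barrier,
                 well_sep = well_sep, friction = friction, kT = kT,
                 dt = dt, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "langevin_spec")
}

#' @rdname langevin_spec
#' @param k_trap Trap stiffness (reduced energy per squared coordinate).
#' @param x0,x1 Trap center start and end positions.
#' @param n_runs Number of independent pulls.
#' @export
toy_schedule <- function(k_trap, x0, x1, n_runs = 20) {
  stopifnot(k_trap > 0, n_runs >= 1)
  structure(list(k_trap = k_trap, x0 = x0, x1 = x1,
                 n_runs = as.integer(n_runs)),
            class = "toy_schedule")
}

toy_force <- function(x, spec) {
  switch(spec$potential,
         flat = 0 * x,
         harmonic = -spec$kappa * x,
         double_well = -4 * spec$barrier * x *
           ((x / spec$well_sep)^2 - 1) / spec$well_sep^2)
}

#' @rdname langevin_spec
#' @param spec A `langevin_spec`.
#' @param sched A `toy_schedule`.
#' @param stride Store every `stride`-th step in the output series.
#' @return `simulate_steered_langevin()`: a long tibble of class
#'   `toy_runs` with columns `run`, `time` (reduced), `cv` (position),
#'   `center` (trap center) and `work` (reduced kT units, accumulated with
#'   the [accumulate_work()] rule); the initial position is drawn from the
#'   trap+potential stationary distribution at `x0`.
#' @export
simulate_steered_langevin <- function(spec, sched, stride = 1L) {
  stopifnot(inherits(spec, "langevin_spec"), inherits(sched, "toy_schedule"))
  stiff <- sched$k_trap + if (spec$potential == "harmonic") spec$kappa else 0
  if (spec$dt * stiff / spec$friction >= 0.1) {
    rlang::abort(sprintf(
      "unstable integration: dt * stiffness / gamma = %.3g >= 0.1; reduce dt below %.3g",
      spec$dt * stiff / spec$friction, 0.1 * spec$friction / stiff))
  }
  n <- spec$n_steps
  m <- sched$n_runs
  centers <- sched$x0 + (sched$x1 - sched$x0) * (0:n) / n
  noise_sd <- sqrt(2 * spec$kT * spec$dt / spec$friction)
  withr::with_seed(spec$seed, {
    # equilibrium start in the trap at x0 (combined stiffness for harmonic V)
    k_eff <- sched$k_trap + if (spec$potential == "harmonic") spec$kappa else 0
    x <- sched$x0 * sched$k_trap / k_eff +
      stats::rnorm(m, 0, sqrt(spec$kT / k_eff))
    w <- numeric(m)
    keep <- seq(0, n, by = stride)
    out_x <- matrix(NA_real_, length(keep), m)
    out_w <- matrix(NA_real_, length(keep), m)
    ki <- 1L
    if (keep[1] == 0) {
      out_x[1, ] <- x
      out_w[1, ] <- w
      ki <- 2L
    }
    for (s in seq_len(n)) {
      c_prev <- centers[s]
      c_new <- centers[s + 1]
      force <- toy_force(x, spec) - sched$k_trap * (x - c_prev)
      x <- x + spec$dt * force / spec$friction +
        noise_sd * stats::rnorm(m)
      # discrete moving-restraint work, same rule as accumulate_work()
      w <- w + sched$k_trap * (c_new - x) * (c_new - c_prev)
      if (ki <= length(keep) && s == keep[ki]) {
        out_x[ki, ] <- x
        out_w[ki, ] <- w
        ki <- ki + 1L
      }
    }
    if (any(!is.finite(x)) || max(abs(x)) > 1e6) {
      rlang::abort(sprintf(
        "trajectory diverged; dt = %g violates the stability bound dt < %.3g",
        spec$dt, 0.1 * spec$friction / stiff))
    }
    out <- tibble::tibble(
      run = rep(seq_len(m), each = length(keep)),
      time = rep(keep * spec$dt, m),
      cv = as.vector(out_x),
      center = rep(centers[keep + 1], m),
      work = as.vector(out_w))
  })
  class(out) <- c("toy_runs", class(out))
  attr(out, "spec") <- spec
  attr(out, "sched") <- sched
  out
}

#' Convert toy runs to work-lambda curves
#'
#' Re-indexes toy trajectories on the normalized steering coordinate
#' (trap center `x0` -> lambda 1, `x1` -> lambda 0) and optionally converts
#' reduced-kT work into kcal/mol at a stated temperature.
#'
#' @param runs A `toy_runs` tibble from [simulate_steered_langevin()].
#' @param energy_unit `"kT"` (leave reduced) or `"kcal/mol"`.
#' @param temperature Temperature used for the kT -> kcal/mol conversion.
#' @return Long work-curve tibble (`run`, `lambda`, `work`) ready for
#'   [jarzynski_pmf()].
#' @export
toy_work_curves <- function(runs, energy_unit = c("kT", "kcal/mol"),
                            temperature = 298) {
  energy_unit <- match.arg(energy_unit)
  sched <- attr(runs, "sched")
  if (is.null(sched)) rlang::abort("`runs` must come from simulate_steered_langevin()")
  lam <- (runs$center - sched$x1) / (sched$x0 - sched$x1)
  w <- runs$work
  if (energy_unit == "kcal/mol") w <- w * kT_kcal(temperature)
  tibble::tibble(run = runs$run, lambda = lam, work = w)
}

#' @rdname simulate_steered_langevin
#' @param runs A `toy_runs` tibble.
#' @param dir Output directory; one COLVAR file per run is written
#'   (`run_001.colvar`, ...), with seed and parameters in header comments.
#' @export
write_toy_colvar <- function(runs, dir) {
  spec <- attr(runs, "spec")
  sched <- attr(runs, "sched")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(sort(unique(runs$run)), function(r) {
    g <- runs[runs$run == r, ]
    p <- file.path(dir, sprintf("run_%03d.colvar", r))
    write_colvar(
      tibble::tibble(time_ps = g$time, cv = g$cv, center = g$center,
                     work = g$work),
      p,
      header = c(
        sprintf("pullpmf toy run %d", r),
        sprintf("seed: %d", spec$seed),
        sprintf("potential: %s k_trap: %g x0: %g x1: %g kT: %g",
                spec$potential, sched$k_trap, sched$x0, sched$x1, spec$kT)))
    p
  })
  invisible(paths)
}

#' Closed-form Gaussian work ensembles
#'
#' Draws terminal work values from `N(mu, sd^2)` and scales them
#' monotonically along a descending lambda grid (work grows as
#' `1 - lambda`), giving an ensemble whose Jarzynski free energy has the
#' exact closed form `mu - beta sd^2 / 2` - the sharpest available oracle
#' for the exponential-average estimator.
#'
#' @param mu,sd Mean and SD of the terminal work (kcal/mol); `sd >= 0`.
#' @param n Number of curves.
#' @param lambda_grid Descending grid from 1 to 0.
#' @param seed Integer seed.
#' @return Long work-curve tibble (`run`, `lambda`, `work`), kcal/mol.
#' @export
gaussian_work_ensemble <- function(mu, sd, n, lambda_grid = seq(1, 0, length.out = 21),
                                   seed = 1L) {
  stopifnot(sd >= 0, n >= 1, all(diff(lambda_grid) < 0))
  terminal <- withr::with_seed(seed, stats::rnorm(n, mu, sd))
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(run = i, lambda = lambda_grid,
                   work = terminal[i] * (1 - lambda_grid))
  })
}

#' Synthetic donor/acceptor point-group complex
#'
#' Builds two rigid point groups - `n_donors` protein donor atoms and
#' `n_acceptors` DNA acceptor atoms - with every donor-acceptor pair at the
#' same prescribed distance, plus the matching [contact_map_spec()]. Pulling
#' the groups apart by `separation` gives an analytically known contact
#' total `n_donors * n_acceptors * switching_value(pair_distance +
#' separation)`.
#'
#' @param n_donors,n_acceptors Group sizes (>= 1).
#' @param pair_distance Donor-acceptor distance at `separation = 0` (nm).
#' @param separation Extra pulling distance added along the z axis (nm).
#' @param switching A [switching_params()].
#' @return A list with elements `structure` (both groups in one
#'   [structure_tbl()], donors on chain "P", acceptors on chain "D"),
#'   `spec`, and `pair_distance_nm` (the realized common distance).
#' @export
synthetic_complex <- function(n_donors, n_acceptors, pair_distance = 0.2,
                              separation = 0, switching = contact_switching()) {
  stopifnot(n_donors >= 1, n_acceptors >= 1, pair_distance > 0, separation >= 0)
  d <- pair_distance + separation
  donors <- tibble::tibble(
    chain = "P", resname = "GLN", resno = seq_len(n_donors),
    atom = "NE2", x = 0, y = 0, z = 0)
  acceptors <- tibble::tibble(
    chain = "D", resname = "DA", resno = seq_len(n_acceptors),
    atom = "N3", x = 0, y = 0, z = d)
  s <- structure_tbl(dplyr::bind_rows(donors, acceptors))
  pairs <- tidyr::expand_grid(dn = seq_len(n_donors), ac = seq_len(n_acceptors))
  spec <- contact_map_spec(tibble::tibble(
    donor = atom_id("P", "GLN", pairs$dn, "NE2"),
    acceptor = atom_id("D", "DA", pairs$ac, "N3"),
    group = sprintf("Q%d", pairs$dn)
  ), switching)
  list(structure = s, spec = spec, pair_distance_nm = d)
}

#' Synthetic B-DNA duplex generator
#'
#' Places phosphates and one groove acceptor atom per base on an ideal
#' cylindrical helix (default rise 0.34 nm, twist 36 degrees, backbone
#' radius 0.94 nm), producing a duplex structure fixture whose cross-strand
#' phosphate geometry is known in closed form. Strand A runs 5'->3' with
#' residues 1..n; strand B holds the reverse complement, numbered 1..n in
#' its own 5'->3' direction so base `i` of A pairs with base `n+1-i` of B.
#' The 5'-terminal residue of each strand carries no phosphate.
#'
#' @param sequence Strand-A base letters, e.g. `"GCAATATATTGC"`.
#' @param rise_nm,twist_deg Helical rise and twist per base pair.
#' @param p_radius_nm Phosphate radial distance from the helix axis.
#' @param strand2_phase_deg Azimuthal offset of the strand-B backbone
#'   relative to strand A at the same base pair (sets the groove widths).
#' @return A [structure_tbl()] with chains "A" and "B".
#' @export
synthetic_duplex <- function(sequence, rise_nm = 0.34, twist_deg = 36,
                             p_radius_nm = 0.94, strand2_phase_deg = 140) {
  bases1 <- strsplit(toupper(sequence), "")[[1]]
  if (!all(bases1 %in% c("A", "T", "G", "C"))) {
    rlang::abort("sequence must contain only A, C, G, T")
  }
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  n <- length(bases1)
  bases2 <- rev(unname(comp[bases1]))  # strand B in its own 5'->3' order
  resname <- c(A = "DA", T = "DT", G = "DG", C = "DC")
  minor_acc <- c(A = "N3", G = "N3", T = "O2", C = "O2")
  major_acc <- c(A = "N7", G = "O6", T = "O4", C = "N4")
  tw <- twist_deg * pi / 180
  ph <- strand2_phase_deg * pi / 180
  mk_strand <- function(chain, bases, angle_at, z_at) {
    purrr::map_dfr(seq_len(n), function(i) {
      b <- bases[i]
      th <- angle_at(i)
      z <- z_at(i)
      rows <- tibble::tibble(
        chain = chain, resname = resname[[b]], resno = i,
        atom = c(minor_acc[[b]], major_acc[[b]], "C1'"),
        x = c(0.30 * cos(th), 0.45 * cos(th + 0.4), 0.60 * cos(th - 0.2)),
        y = c(0.30 * sin(th), 0.45 * sin(th + 0.4), 0.60 * sin(th - 0.2)),
        z = z)
      if (i > 1) {  # 5' terminus has no phosphate
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          chain = chain, resname = resname[[b]], resno = i, atom = "P",
          x = p_radius_nm * cos(th), y = p_radius_nm * sin(th), z = z))
      }
      rows
    })
  }
  # strand A: base-pair index i at angle i*tw, height i*rise
  sA <- mk_strand("A", bases1, function(i) i * tw, function(i) i * rise_nm)
  # strand B residue k sits at base pair j = n + 1 - k
  sB <- mk_strand("B", bases2,
                  function(k) (n + 1 - k) * tw + ph,
                  function(k) (n + 1 - k) * rise_nm)
  structure_tbl(dplyr::bind_rows(sA, sB))
}

#' Synthetic H-NS DNA-binding-domain stand-in
#'
#' A minimal synthetic protein fragment carrying the residues and donor
#' atoms of the H-NS QGR motif and R93 (GLN112 N/NE2, GLY113 N, ARG114 and
#' ARG93 N/NE/NH1/NH2, plus CA placeholders), positioned near the origin.
#' It is a geometric stand-in for testing selection and contact-map
#' construction, not a structural model of the domain.
#'
#' @param offset_nm Translation applied to all atoms (length-3, nm).
#' @return A [structure_tbl()] on chain "H".
#' @export
synthetic_hns_dbd <- function(offset_nm = c(0, 0, 0)) {
  res <- list(
    list(resno = 93, resname = "ARG", atoms = c("N", "CA", "NE", "NH1", "NH2")),
    list(resno = 112, resname = "GLN", atoms = c("N", "CA", "NE2")),
    list(resno = 113, resname = "GLY", atoms = c("N", "CA")),
    list(resno = 114, resname = "ARG", atoms = c("N", "CA", "NE", "NH1", "NH2"))
  )
  atoms <- purrr::imap_dfr(res, function(r, i) {
    k <- length(r$atoms)
    tibble::tibble(
      chain = "H", resname = r$resname, resno = r$resno, atom = r$atoms,
      x = offset_nm[1] + 0.4 * i + 0.05 * seq_len(k),
      y = offset_nm[2] + 0.05 * seq_len(k),
      z = offset_nm[3] + 0.1 * i)
  })
  structure_tbl(atoms)
}
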