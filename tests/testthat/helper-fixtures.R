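# shared fixtures, all generated in code

# a contact-map spec over a small synthetic donor/acceptor grid, with
# distances attached, for contact-arithmetic tests
make_grid_spec <- function(n_donors = 2, n_acceptors = 3,
                           switching = contact_switching()) {
  cx <- synthetic_complex(n_donors, n_acceptors, switching = switching)
  cx
}

# distances tibble covering every pair of a spec, all equal to r
uniform_distances <- function(spec, r) {
  if (!inherits(spec, "contact_map_spec")) spec <- spec$spec
  tibble::tibble(donor = spec$pairs$donor,
                 acceptor = spec$pairs$acceptor,
                 r_nm = r)
}

# one synthetic steered run whose total contact count decays linearly and
# whose Q112 count reaches `cq_at_cross` exactly when total = 30
make_pathway_curve <- function(run, cq_at_cross, t = seq(0, 1, by = 0.05),
                               total_start = 40, total_end = 15,
                               q_start = 11) {
  total <- total_start + (total_end - total_start) * t
  t_cross <- (total_start - 30) / (total_start - total_end)
  cq <- q_start + (cq_at_cross - q_start) / t_cross * pmin(t, t_cross)
  tibble::tibble(run = run, time_ps = t, total = total, Q112 = cq,
                 R114 = total - cq)
}

# rigid rotation + translation of a structure's coordinates
rigid_transform <- function(s, angles = c(0.3, -0.8, 1.2),
                            shift = c(1, -2, 0.5)) {
  rot <- function(a, i, j) {
    R <- diag(3)
    R[i, i] <- cos(a); R[j, j] <- cos(a)
    R[i, j] <- -sin(a); R[j, i] <- sin(a)
    R
  }
  R <- rot(angles[1], 1, 2) %*% rot(angles[2], 2, 3) %*% rot(angles[3], 1, 3)
  xyz <- cbind(s$x, s$y, s$z) %*% t(R)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

# analytic cross-strand P-P minimum for the ideal cylindrical duplex:
# both phosphates sit on a radius-R cylinder; the distance between points
# separated by angle dth and height dz is sqrt(2 R^2 (1 - cos dth) + dz^2)
ideal_groove_width_oracle <- function(radius = 0.94, rise = 0.34,
                                      twist_deg = 36, phase_deg = 140,
                                      offset = 0.58, registers = c(-3, -2, -1)) {
  tw <- twist_deg * pi / 180
  ph <- phase_deg * pi / 180
  d <- vapply(-registers, function(o) {
    dth <- o * tw - ph
    dz <- o * rise
    sqrt(2 * radius^2 * (1 - cos(dth)) + dz^2)
  }, numeric(1))
  min(d) - offset
}
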