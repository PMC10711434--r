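#' Molecular structures as tibbles
#'
#' A structure is a tibble with one row per atom and columns `chain`,
#' `resname`, `resno`, `atom`, `element`, `eleno` (file serial) and
#' coordinates `x`, `y`, `z` in nanometres, carrying an optional `box`
#' attribute (3 box lengths, nm). `(chain, resno, atom)` triplets must be
#' unique and all coordinates finite.
#'
#' @param atoms A data frame with the columns above.
#' @param box Optional numeric length-3 box vector in nm.
#' @return A tibble of class `pullpmf_structure`.
#' @export
structure_tbl <- function(atoms, box = NULL) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("chain", "resname", "resno", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    rlang::abort(paste("structure needs columns:", paste(need, collapse = ", ")))
  }
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$atom)
  if (!"eleno" %in% names(atoms)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$resno <- as.integer(atoms$resno)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    rlang::abort("non-finite coordinates in structure")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    rlang::abort(sprintf("duplicate atom triplet (chain, resno, atom): %s",
                         key[duplicated(key)][1]))
  }
  out <- atoms[c("chain", "resname", "resno", "atom", "element", "eleno",
                 "x", "y", "z")]
  attr(out, "box") <- box
  class(out) <- c("pullpmf_structure", class(out))
  out
}

is_structure <- function(x) inherits(x, "pullpmf_structure")

guess_element <- function(atom) {
  e <- substr(gsub("[0-9']", "", atom), 1, 1)
  ifelse(e == "", "X", e)
}

#' @rdname structure_tbl
#' @param s A structure tibble.
#' @export
structure_ids <- function(s) {
  atom_id(s$chain, s$resname, s$resno, s$atom)
}

#' Read a structure file
#'
#' Reads PDB (via bio3d; coordinates converted from Angstrom to nm) or
#' GROMACS GRO (fixed-width parser; already in nm). Residue-name dialects
#' for nucleotides (DA/ADE/A, ...) are preserved verbatim on read and
#' normalized only inside the selection helpers.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return A [structure_tbl()] tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", ent = "pdb", gro = "gro",
                     rlang::abort(sprintf("cannot infer format of %s", path)))
  }
  switch(format, pdb = read_structure_pdb(path), gro = read_structure_gro(path))
}

read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  structure_tbl(tibble::tibble(
    chain = chain, resname = a$resid, resno = a$resno, atom = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     guess_element(a$elety), a$elesy),
    eleno = a$eleno,
    x = a$x / 10, y = a$y / 10, z = a$z / 10
  ))
}

read_structure_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) rlang::abort(sprintf("%s: truncated GRO file", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) rlang::abort(sprintf("%s line 2: expected atom count", path))
  if (length(lines) < 2 + n + 1) {
    rlang::abort(sprintf("%s: expected %d atom lines", path, n))
  }
  al <- lines[3:(2 + n)]
  num <- function(s, i) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      rlang::abort(sprintf("%s line %d: malformed GRO record",
                           path, 2 + which(is.na(v))[1]))
    }
    v
  }
  resno <- num(trimws(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  atom <- trimws(substr(al, 11, 15))
  eleno <- num(trimws(substr(al, 16, 20)))
  x <- num(trimws(substr(al, 21, 28)))
  y <- num(trimws(substr(al, 29, 36)))
  z <- num(trimws(substr(al, 37, 44)))
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  box <- if (length(box) >= 3 && !anyNA(box[1:3])) box[1:3] else NULL
  structure_tbl(tibble::tibble(
    chain = "A", resname = resname, resno = as.integer(resno),
    atom = atom, eleno = as.integer(eleno), x = x, y = y, z = z,
    element = guess_element(atom)
  ), box = box)
}

#' Write a structure as a PDB snapshot
#'
#' Coordinates are converted from nm to Angstrom on write.
#'
#' @param s A [structure_tbl()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(is_structure(s))
  an <- ifelse(nchar(s$atom) < 4, sprintf(" %-3s", s$atom), s$atom)
  rec <- sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 s$eleno, an, s$resname, substr(s$chain, 1, 1), s$resno,
                 s$x * 10, s$y * 10, s$z * 10, 1.0, 0.0, s$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Trajectories
#'
#' A trajectory couples a topology (a [structure_tbl()]) with an
#' `n_frames x (3 n_atoms)` coordinate matrix in nm (bio3d xyz layout) and
#' strictly increasing frame times in ps.
#'
#' @param topology A [structure_tbl()].
#' @param xyz Coordinate matrix, one row per frame, in nm.
#' @param times Frame times in ps; defaults to `0, dt, 2 dt, ...`.
#' @param dt Frame spacing in ps used when `times` is absent.
#' @return An object of class `pullpmf_trajectory`.
#' @export
trajectory <- function(topology, xyz, times = NULL, dt = 20) {
  stopifnot(is_structure(topology))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(topology)) {
    rlang::abort("frame width does not match topology atom count")
  }
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * dt
  if (length(times) != nrow(xyz) || any(diff(times) <= 0)) {
    rlang::abort("`times` must match frame count and increase strictly")
  }
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "pullpmf_trajectory")
}

is_trajectory <- function(x) inherits(x, "pullpmf_trajectory")

#' @export
print.pullpmf_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              nrow(x$xyz), nrow(x$topology), min(x$times), max(x$times)))
  invisible(x)
}

#' @rdname trajectory
#' @param traj A trajectory.
#' @param i Frame index (1-based; frames are counted from the first stored
#'   frame at index 1, reported externally as frame `i - 1`).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(is_trajectory(traj))
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' @rdname trajectory
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Read a trajectory
#'
#' Supports DCD (via bio3d, Angstrom converted to nm) and multi-model PDB
#' (MODEL/ENDMDL blocks). For DCD a topology structure must be supplied.
#'
#' @param path Trajectory file.
#' @param topology Topology [structure_tbl()]; required for DCD, optional
#'   for multi-model PDB (first model is used when absent).
#' @param format `"auto"`, `"dcd"` or `"pdb"`.
#' @inheritParams trajectory
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "dcd", "pdb"),
                            times = NULL, dt = 20) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     dcd = "dcd", pdb = "pdb",
                     rlang::abort(sprintf("cannot infer format of %s", path)))
  }
  if (format == "dcd") {
    if (is.null(topology)) rlang::abort("DCD trajectories need a `topology`")
    xyz <- bio3d::read.dcd(path, verbose = FALSE) / 10
    return(trajectory(topology, xyz, times = times, dt = dt))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(topology)) topology <- read_structure_pdb(path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory(topology, xyz / 10, times = times, dt = dt)
}

resolve_atoms <- function(s, ids) {
  sid <- structure_ids(s)
  idx <- match(ids, sid)
  if (anyNA(idx)) {
    rlang::abort(sprintf("atom %s not found in structure", ids[is.na(idx)][1]))
  }
  idx
}

#' Donor-acceptor distances for a contact map
#'
#' Computes the distance in nm of every pair in the spec from a structure or
#' a single trajectory frame. By default distances are computed without
#' periodic-boundary minimum-image wrapping: as the complex is pulled apart
#' a periodic image may come closer than the real partner, which would
#' corrupt the steering coordinate. Set `pbc = TRUE` (with an orthorhombic
#' `box`) for minimum-image distances in other applications.
#'
#' @param s A [structure_tbl()], or a trajectory with `frame`.
#' @param spec A [contact_map_spec()].
#' @param pbc Apply orthorhombic minimum-image wrapping?
#' @param box Box lengths (nm); defaults to the structure's box attribute.
#' @param frame Frame index when `s` is a trajectory.
#' @return A tibble with columns `donor`, `acceptor`, `r_nm`.
#' @export
pair_distances <- function(s, spec, pbc = FALSE, box = NULL, frame = 1) {
  stopifnot(is_contact_map_spec(spec))
  if (is_trajectory(s)) {
    xyz <- frame_coords(s, frame)
    top <- s$topology
  } else {
    stopifnot(is_structure(s))
    xyz <- cbind(s$x, s$y, s$z)
    top <- s
    if (is.null(box)) box <- attr(s, "box")
  }
  di <- resolve_atoms(top, spec$pairs$donor)
  ai <- resolve_atoms(top, spec$pairs$acceptor)
  d <- xyz[di, , drop = FALSE] - xyz[ai, , drop = FALSE]
  if (pbc) {
    if (is.null(box) || length(box) < 3) {
      rlang::abort("`pbc = TRUE` requires a box")
    }
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  tibble::tibble(donor = spec$pairs$donor, acceptor = spec$pairs$acceptor,
                 r_nm = sqrt(rowSums(d^2)))
}

#' Per-frame contact counts along a trajectory
#'
#' Evaluates the contact map on every frame, returning one row per frame
#' with the time, each donor group's contact count, and the total.
#'
#' @inheritParams pair_distances
#' @param traj A [trajectory()].
#' @return A tibble with columns `frame` (0-based), `time_ps`, one column
#'   per donor group, and `total`.
#' @export
contact_series <- function(traj, spec, pbc = FALSE, box = NULL) {
  stopifnot(is_trajectory(traj), is_contact_map_spec(spec))
  top <- traj$topology
  di <- resolve_atoms(top, spec$pairs$donor)
  ai <- resolve_atoms(top, spec$pairs$acceptor)
  groups <- contact_groups(spec)
  gidx <- match(spec$pairs$group, groups)
  nf <- n_frames(traj)
  per <- matrix(0, nf, length(groups), dimnames = list(NULL, groups))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    d <- xyz[di, , drop = FALSE] - xyz[ai, , drop = FALSE]
    if (pbc) {
      b <- if (is.null(box)) attr(top, "box") else box
      if (is.null(b)) rlang::abort("`pbc = TRUE` requires a box")
      for (k in 1:3) d[, k] <- d[, k] - b[k] * round(d[, k] / b[k])
    }
    w <- switching_value(sqrt(rowSums(d^2)), spec$switching)
    per[f, ] <- vapply(seq_along(groups),
                       function(g) sum(w[gidx == g]), numeric(1))
  }
  out <- tibble::as_tibble(per)
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(nf) - 1L, time_ps = traj$times),
    out,
    tibble::tibble(total = rowSums(per))
  )
}

kabsch_rmsd <- function(X, Y) {
  # optimal-superposition RMSD of two n x 3 coordinate sets
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))                 # H = X^T Y
  d <- sign(det(s$u) * det(s$v))              # avoid improper rotations
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
}

#' Optimal-superposition RMSD along a trajectory
#'
#' Root-mean-square deviation of an atom subset from a reference structure,
#' per frame, after removing rigid rotation and translation (Kabsch
#' superposition via singular value decomposition).
#'
#' @param traj A [trajectory()].
#' @param reference A [structure_tbl()] holding the reference coordinates.
#' @param subset Atom id strings (see [atom_id()]) present in both the
#'   trajectory topology and the reference; defaults to all reference atoms.
#' @return A tibble with columns `frame` (0-based), `time_ps`, `rmsd_nm`.
#' @export
rmsd_series <- function(traj, reference, subset = NULL) {
  stopifnot(is_trajectory(traj), is_structure(reference))
  if (is.null(subset)) subset <- structure_ids(reference)
  ri <- resolve_atoms(reference, subset)
  ti <- resolve_atoms(traj$topology, subset)
  ref <- cbind(reference$x, reference$y, reference$z)[ri, , drop = FALSE]
  nf <- n_frames(traj)
  r <- vapply(seq_len(nf), function(f) {
    kabsch_rmsd(frame_coords(traj, f)[ti, , drop = FALSE], ref)
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf) - 1L, time_ps = traj$times, rmsd_nm = r)
}

#' @rdname rmsd_series
#' @param series The tibble returned by `rmsd_series()`.
#' @param path Output TSV path.
#' @export
write_rmsd_tsv <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
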