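#' Atom identifier strings
#'
#' Atoms are addressed throughout by compact identifier strings of the form
#' `"chain/RESNAMEresno/ATOM"`, e.g. `"A/GLN112/NE2"` or `"B/DT7/O2"`.
#' `atom_id()` builds them from components; `atom_id_parts()` splits them
#' back into a tibble.
#'
#' @param chain Chain identifier.
#' @param resname Residue name (PDB style).
#' @param resno Residue number.
#' @param atom Atom name.
#' @return `atom_id()`: character vector; `atom_id_parts()`: tibble with
#'   columns `chain`, `resname`, `resno`, `atom`.
#' @export
atom_id <- function(chain, resname, resno, atom) {
  sprintf("%s/%s%d/%s", as.character(chain), as.character(resname),
          as.integer(resno), as.character(atom))
}

#' @rdname atom_id
#' @param id Identifier string(s) produced by `atom_id()`.
#' @export
atom_id_parts <- function(id) {
  m <- regmatches(id, regexec("^([^/]+)/([A-Za-z0-9']+?)(-?[0-9]+)/(.+)$", id))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    rlang::abort(paste0("malformed atom id: ", paste(id[bad], collapse = ", ")))
  }
  tibble::tibble(
    chain   = vapply(m, `[[`, "", 2),
    resname = vapply(m, `[[`, "", 3),
    resno   = as.integer(vapply(m, `[[`, "", 4)),
    atom    = vapply(m, `[[`, "", 5)
  )
}

residue_of <- function(id) sub("/[^/]+$", "", id)

#' Contact-map specification
#'
#' Bundles the donor-acceptor pair list, the switching function parameters,
#' and the per-donor grouping that together define the contact-map collective
#' variable: the total contact count is the switching-weighted sum over all
#' pairs, and per-donor counts (e.g. for Q112, G113, R114 of the H-NS QGR
#' motif) are sums over the group's pairs.
#'
#' @param pairs A data frame with columns `donor`, `acceptor` (atom id
#'   strings, see [atom_id()]) and `group` (donor group label, e.g. "Q112").
#'   Optional integer columns `donor_eleno` / `acceptor_eleno` carry engine
#'   atom serials for steering-input emission.
#' @param switching A [switching_params()] object.
#' @return An object of class `contact_map_spec`.
#' @details Each pair belongs to exactly one group, and at most one acceptor
#'   atom is used per nucleobase (so contact totals are comparable between
#'   sequences); both invariants are enforced at construction.
#' @seealso [contact_total()], [build_contact_map()]
#' @export
contact_map_spec <- function(pairs, switching) {
  if (!is_switching_params(switching)) {
    rlang::abort("`switching` must be a switching_params object")
  }
  pairs <- tibble::as_tibble(pairs)
  need <- c("donor", "acceptor", "group")
  if (!all(need %in% names(pairs))) {
    rlang::abort("`pairs` needs columns donor, acceptor, group")
  }
  if (nrow(pairs) == 0) rlang::abort("`pairs` must contain at least one pair")
  if (any(pairs$donor == pairs$acceptor)) {
    rlang::abort("donor and acceptor of a pair must be distinct atoms")
  }
  if (anyDuplicated(pairs[c("donor", "acceptor")])) {
    rlang::abort("duplicate donor-acceptor pair in spec")
  }
  # one acceptor atom per nucleobase
  acc <- unique(pairs$acceptor)
  base <- residue_of(acc)
  if (anyDuplicated(base)) {
    dup <- base[duplicated(base)][1]
    rlang::abort(sprintf(
      "nucleobase %s contributes more than one acceptor atom; limit is one per base", dup))
  }
  structure(list(pairs = pairs, switching = switching),
            class = "contact_map_spec")
}

#' @export
print.contact_map_spec <- function(x, ...) {
  cat(sprintf("<contact_map_spec> %d pairs in %d donor groups\n",
              nrow(x$pairs), dplyr::n_distinct(x$pairs$group)))
  print(x$switching)
  invisible(x)
}

is_contact_map_spec <- function(x) inherits(x, "contact_map_spec")

#' @rdname contact_map_spec
#' @param x Object to test or print.
#' @export
contact_groups <- function(x) {
  stopifnot(is_contact_map_spec(x))
  unique(x$pairs$group)
}

join_distances <- function(distances, spec) {
  distances <- tibble::as_tibble(distances)
  if (!all(c("donor", "acceptor", "r_nm") %in% names(distances))) {
    rlang::abort("`distances` needs columns donor, acceptor, r_nm")
  }
  j <- dplyr::left_join(spec$pairs, distances, by = c("donor", "acceptor"))
  if (anyNA(j$r_nm)) {
    miss <- j[is.na(j$r_nm), ]
    rlang::abort(sprintf(
      "no distance supplied for pair %s - %s",
      miss$donor[1], miss$acceptor[1]))
  }
  j
}

#' Total and per-donor contact counts
#'
#' `contact_total()` sums the switching-weighted contacts over every pair in
#' the spec, giving the dimensionless contact count that serves as the
#' collective variable. `contact_per_donor()` restricts the sum to one donor
#' group; per-donor counts partition the total exactly.
#' `contact_table()` returns the per-group decomposition plus the total in
#' one tibble.
#'
#' @param distances A data frame with columns `donor`, `acceptor`, `r_nm`
#'   giving the distance in nm of every pair in the spec.
#' @param spec A [contact_map_spec()].
#' @param group A donor group label present in the spec.
#' @return `contact_total()`: a single number in `[0, n_pairs]`;
#'   `contact_per_donor()`: a single number; `contact_table()`: a tibble
#'   with columns `group` and `contacts`.
#' @export
contact_total <- function(distances, spec) {
  stopifnot(is_contact_map_spec(spec))
  j <- join_distances(distances, spec)
  sum(switching_value(j$r_nm, spec$switching))
}

#' @rdname contact_total
#' @export
contact_per_donor <- function(distances, spec, group) {
  stopifnot(is_contact_map_spec(spec))
  labels <- contact_groups(spec)
  if (!group %in% labels) {
    rlang::abort(sprintf("unknown donor group '%s'; valid groups: %s",
                         group, paste(labels, collapse = ", ")))
  }
  j <- join_distances(distances, spec)
  j <- j[j$group == group, ]
  sum(switching_value(j$r_nm, spec$switching))
}

#' @rdname contact_total
#' @export
contact_table <- function(distances, spec) {
  stopifnot(is_contact_map_spec(spec))
  j <- join_distances(distances, spec)
  j$w <- switching_value(j$r_nm, spec$switching)
  out <- dplyr::summarise(dplyr::group_by(j, .data$group),
                          contacts = sum(.data$w), .groups = "drop")
  dplyr::bind_rows(out, tibble::tibble(group = "total",
                                       contacts = sum(j$w)))
}

#' Normalized linear steering coordinate
#'
#' The steering coordinate lambda is an affine rescaling of the contact
#' count: `lambda = (C - c_end) / (c_start - c_end)`, so `c_start` (the
#' fully inserted bound state) maps to 1 and `c_end` (the backbone-bound,
#' dissociated state) maps to 0. Values are deliberately not clamped;
#' excursions outside `[0, 1]` are flagged with a warning. The same map must
#' be shared across systems whose free-energy profiles are to be compared.
#'
#' @param c_start Contact count mapped to lambda = 1.
#' @param c_end Contact count mapped to lambda = 0; must differ from
#'   `c_start` (and be smaller for a dissociation pull).
#' @return `lambda_map()`: an object of class `lambda_map`.
#' @examples
#' m <- lambda_map(108, 65)
#' lambda_of_contacts(c(108, 86.5, 65), m)
#' @export
lambda_map <- function(c_start, c_end) {
  stopifnot(is.numeric(c_start), is.numeric(c_end),
            is.finite(c_start), is.finite(c_end))
  if (c_start <= c_end) rlang::abort("`c_start` must exceed `c_end`")
  structure(list(c_start = c_start, c_end = c_end), class = "lambda_map")
}

is_lambda_map <- function(x) inherits(x, "lambda_map")

#' @rdname lambda_map
#' @param C Contact count(s).
#' @param map A `lambda_map` object.
#' @export
lambda_of_contacts <- function(C, map) {
  if (!is_lambda_map(map)) rlang::abort("`map` must be a lambda_map")
  lam <- (C - map$c_end) / (map$c_start - map$c_end)
  if (any(lam < 0 | lam > 1, na.rm = TRUE)) {
    rlang::warn("lambda values outside [0, 1]; contact count left the steering range",
                class = "pullpmf_lambda_range")
  }
  lam
}

#' @rdname lambda_map
#' @param lambda Steering-coordinate value(s).
#' @export
contacts_of_lambda <- function(lambda, map) {
  if (!is_lambda_map(map)) rlang::abort("`map` must be a lambda_map")
  map$c_end + lambda * (map$c_start - map$c_end)
}

#' Read and write contact-map specifications
#'
#' The spec is serialized to a nested YAML file (switching parameters plus
#' one record per pair); `write_contact_tsv()` additionally dumps a
#' human-readable TSV of (donor, acceptor, group) for auditing.
#'
#' @param spec A [contact_map_spec()].
#' @param path File path.
#' @return `read_contact_map()` returns a `contact_map_spec`; the writers
#'   return `path` invisibly.
#' @export
write_contact_map <- function(spec, path) {
  stopifnot(is_contact_map_spec(spec))
  obj <- list(
    switching = list(r0 = spec$switching$r0, d0 = spec$switching$d0,
                     nn = spec$switching$nn, mm = spec$switching$mm),
    pairs = purrr::pmap(spec$pairs, function(...) list(...))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$switching) || is.null(obj$pairs)) {
    rlang::abort(sprintf("%s is not a contact-map file", path))
  }
  sw <- obj$switching
  pairs <- dplyr::bind_rows(lapply(obj$pairs, tibble::as_tibble))
  contact_map_spec(pairs, switching_params(sw$r0, sw$d0, sw$nn, sw$mm))
}

#' @rdname write_contact_map
#' @export
write_contact_tsv <- function(spec, path) {
  stopifnot(is_contact_map_spec(spec))
  utils::write.table(spec$pairs[c("donor", "acceptor", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
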