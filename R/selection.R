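# residue-name dialect tables -------------------------------------------------

NUC_ALIASES <- c(
  DA = "A", DA3 = "A", DA5 = "A", ADE = "A", A = "A", RA = "A",
  DT = "T", DT3 = "T", DT5 = "T", THY = "T", T = "T",
  DG = "G", DG3 = "G", DG5 = "G", GUA = "G", G = "G", RG = "G",
  DC = "C", DC3 = "C", DC5 = "C", CYT = "C", C = "C", RC = "C",
  DU = "U", URA = "U", U = "U"
)

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# heavy side-chain / backbone atoms per amino acid, for nearest-name hints
AA_ATOMS <- list(
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLY = c("N", "CA", "C", "O"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")
)

normalize_base <- function(resname) {
  key <- toupper(resname)
  out <- unname(NUC_ALIASES[key])
  out
}

#' Groove hydrogen-bond acceptor selection
#'
#' Selects exactly one hydrogen-bond acceptor atom per nucleobase, so
#' contact totals are comparable between DNA sequences. Minor-groove
#' convention: purines (A, G) contribute N3, pyrimidines (T, C) contribute
#' O2. Major-groove convention: G contributes O6, A contributes N7 and T
#' contributes O4; cytosine presents only the N4 amino donor in the major
#' groove and therefore contributes no default acceptor (override via
#' `acceptor_map` to include it).
#'
#' @param s A [structure_tbl()].
#' @param residues A data frame with columns `chain` and `resno` naming the
#'   bases (on both strands) to include.
#' @param acceptor_map Named character vector base letter -> atom name,
#'   overriding the convention (e.g. `c(C = "N4")`).
#' @return A tibble with columns `chain`, `resname`, `resno`, `atom`, `base`
#'   and `id` (atom identifier string), one row per contributing base.
#' @export
select_minor_groove_acceptors <- function(s, residues, acceptor_map = NULL) {
  amap <- c(A = "N3", G = "N3", T = "O2", C = "O2", U = "O2")
  if (!is.null(acceptor_map)) amap[names(acceptor_map)] <- acceptor_map
  select_groove_acceptors(s, residues, amap, groove = "minor")
}

#' @rdname select_minor_groove_acceptors
#' @export
select_major_groove_acceptors <- function(s, residues, acceptor_map = NULL) {
  amap <- c(G = "O6", A = "N7", T = "O4", C = NA_character_, U = "O4")
  if (!is.null(acceptor_map)) amap[names(acceptor_map)] <- acceptor_map
  select_groove_acceptors(s, residues, amap, groove = "major")
}

select_groove_acceptors <- function(s, residues, amap, groove) {
  stopifnot(is_structure(s))
  residues <- tibble::as_tibble(residues)
  if (!all(c("chain", "resno") %in% names(residues))) {
    rlang::abort("`residues` needs columns chain and resno")
  }
  out <- purrr::pmap_dfr(residues, function(chain, resno, ...) {
    rows <- s[s$chain == chain & s$resno == resno, ]
    if (nrow(rows) == 0) {
      rlang::abort(sprintf("residue %s:%d not in structure", chain, resno))
    }
    resname <- rows$resname[1]
    base <- normalize_base(resname)
    if (is.na(base)) {
      rlang::abort(sprintf("residue %s:%d (%s) is not a standard nucleotide",
                           chain, resno, resname))
    }
    atom <- amap[[base]]
    if (is.na(atom)) return(NULL)  # base has no acceptor in this groove
    if (!atom %in% rows$atom) {
      rlang::abort(sprintf(
        "base %s:%d (%s) is missing expected %s-groove acceptor atom %s",
        chain, resno, resname, groove, atom))
    }
    tibble::tibble(chain = chain, resname = resname, resno = resno,
                   atom = atom, base = base)
  })
  out <- dplyr::distinct(out)
  out$id <- atom_id(out$chain, out$resname, out$resno, out$atom)
  out
}

#' Default H-NS DNA-binding-domain donor preset
#'
#' Hydrogen-bond donors of the conserved QGR loop (Q112: backbone N and
#' side-chain NE2; G113: backbone N; R114: backbone N plus guanidinium NE,
#' NH1, NH2) and of R93 (same arginine donor set). Arginine has no NZ atom;
#' requests for NZ on an arginine are remapped to NE with a warning.
#'
#' @return A named list residue label -> atom-name vector, the `spec`
#'   argument of [select_protein_donors()].
#' @export
hns_donor_preset <- function() {
  list(
    Q112 = c("N", "NE2"),
    G113 = c("N"),
    R114 = c("N", "NE", "NH1", "NH2"),
    R93  = c("N", "NE", "NH1", "NH2")
  )
}

parse_residue_label <- function(label) {
  m <- regexec("^([A-Za-z])(-?[0-9]+)$", label)[[1]]
  if (m[1] == -1) rlang::abort(sprintf("cannot parse residue label '%s'", label))
  aa1 <- toupper(substr(label, m[2], m[2]))
  list(one = aa1, three = unname(AA_ONE_TO_THREE[aa1]),
       resno = as.integer(sub("^[A-Za-z]", "", label)))
}

#' Protein hydrogen-bond donor selection
#'
#' Resolves residue-label -> atom-name requests (e.g. `Q112 = c("N",
#' "NE2")`) against a structure, returning identifiers grouped by residue
#' label. An absent atom raises an error with the nearest valid atom name
#' as a hint; the non-existent arginine NZ is remapped to NE with a warning.
#'
#' @param s A [structure_tbl()].
#' @param spec Named list residue label -> atom names; see
#'   [hns_donor_preset()].
#' @param chain Chain holding the protein (default first chain with amino
#'   acids matching the labels).
#' @return A tibble with columns `group`, `chain`, `resname`, `resno`,
#'   `atom`, `id`.
#' @export
select_protein_donors <- function(s, spec, chain = NULL) {
  stopifnot(is_structure(s))
  if (length(spec) == 0) {
    return(tibble::tibble(group = character(), chain = character(),
                          resname = character(), resno = integer(),
                          atom = character(), id = character()))
  }
  purrr::imap_dfr(spec, function(atoms, label) {
    p <- parse_residue_label(label)
    rows <- s[s$resno == p$resno, ]
    if (!is.null(chain)) rows <- rows[rows$chain == chain, ]
    rows <- rows[toupper(rows$resname) == p$three, ]
    if (nrow(rows) == 0) {
      rlang::abort(sprintf("residue %s (%s %d) not found in structure",
                           label, p$three, p$resno))
    }
    resolved <- vapply(atoms, function(a) {
      if (a %in% rows$atom) return(a)
      if (toupper(a) == "NZ" && p$three == "ARG") {
        rlang::warn(sprintf(
          "%s: arginine has no NZ atom; remapping NZ -> NE", label),
          class = "pullpmf_nz_remap")
        return("NE")
      }
      valid <- if (p$three %in% names(AA_ATOMS)) AA_ATOMS[[p$three]] else rows$atom
      near <- valid[which.min(utils::adist(a, valid))]
      rlang::abort(sprintf(
        "residue %s has no atom '%s'; nearest valid name: %s", label, a, near))
    }, character(1))
    resolved <- unique(resolved)
    idx <- match(resolved, rows$atom)
    tibble::tibble(group = label, chain = rows$chain[idx],
                   resname = rows$resname[idx], resno = rows$resno[idx],
                   atom = resolved,
                   id = atom_id(rows$chain[idx], rows$resname[idx],
                                rows$resno[idx], resolved))
  })
}

#' Build a contact map from donor and acceptor selections
#'
#' Forms the full donor x acceptor pair list (every donor paired with every
#' acceptor), grouped by donor residue label, and wraps it with switching
#' parameters into a [contact_map_spec()]. Engine atom serials (`eleno`)
#' are carried along for steering-input emission.
#'
#' @param donors Tibble from [select_protein_donors()].
#' @param acceptors Tibble from [select_minor_groove_acceptors()] or
#'   [select_major_groove_acceptors()].
#' @param switching A [switching_params()]; defaults to the descriptive
#'   contact set.
#' @param structure Optional [structure_tbl()] used to attach atom serials.
#' @return A [contact_map_spec()].
#' @export
build_contact_map <- function(donors, acceptors,
                              switching = contact_switching(),
                              structure = NULL) {
  if (nrow(donors) == 0 || nrow(acceptors) == 0) {
    rlang::abort("need at least one donor and one acceptor")
  }
  grid <- tidyr::expand_grid(d = seq_len(nrow(donors)),
                             a = seq_len(nrow(acceptors)))
  pairs <- tibble::tibble(
    donor = donors$id[grid$d],
    acceptor = acceptors$id[grid$a],
    group = donors$group[grid$d]
  )
  if (!is.null(structure)) {
    pairs$donor_eleno <- structure$eleno[resolve_atoms(structure, pairs$donor)]
    pairs$acceptor_eleno <- structure$eleno[resolve_atoms(structure, pairs$acceptor)]
  }
  contact_map_spec(pairs, switching)
}
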