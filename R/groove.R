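#' Minor-groove width profile from cross-strand phosphate distances
#'
#' Computes a per-base-pair-step minor-groove width as the minimum
#' cross-strand phosphate-phosphate distance, minus 0.58 nm (twice the
#' phosphate van-der-Waals radius). For the strand-1 phosphate at base-pair
#' index `i`, strand-2 phosphates at base-pair indices `i - 3`, `i - 2`
#' and `i - 1` are considered (the register offsets that span the minor
#' groove in B-DNA). This is a deliberate simplification of curvilinear
#' helical-axis groove definitions: it tracks relative narrowing and
#' widening without fitting an axis. Positions whose phosphates are missing
#' (5' termini carry no P) are reported as `NA`, not zero.
#'
#' Base pairing is positional: residue `i` (5'->3') on strand 1 pairs with
#' residue `n + 1 - i` (5'->3') on strand 2, so both chains must contain
#' the same number of nucleotides.
#'
#' @param x A [structure_tbl()] or [trajectory()].
#' @param chain1,chain2 Chain identifiers of the two strands.
#' @param offset_nm Subtracted phosphate-diameter correction (nm).
#' @param registers Strand-2 base-pair-index offsets scanned for the
#'   minimum distance.
#' @return A tibble with columns `frame` (0-based; 0 for a structure),
#'   `time_ps`, `step` (base-pair index of the strand-1 phosphate) and
#'   `width_nm` (`NA` where undefined).
#' @seealso [groove_profile_mean()]
#' @export
minor_groove_width <- function(x, chain1 = "A", chain2 = "B",
                               offset_nm = 0.58, registers = c(-3, -2, -1)) {
  if (is_structure(x)) {
    top <- x
    frames <- list(cbind(x$x, x$y, x$z))
    times <- 0
  } else if (is_trajectory(x)) {
    top <- x$topology
    frames <- lapply(seq_len(n_frames(x)), function(f) frame_coords(x, f))
    times <- x$times
  } else {
    rlang::abort("`x` must be a structure or trajectory")
  }
  s1 <- top[top$chain == chain1 & !is.na(normalize_base(top$resname)), ]
  s2 <- top[top$chain == chain2 & !is.na(normalize_base(top$resname)), ]
  res1 <- sort(unique(s1$resno))
  res2 <- sort(unique(s2$resno))
  n <- length(res1)
  if (n < 2 || length(res2) != n) {
    rlang::abort("input is not a duplex: strands must hold equal numbers of nucleotides")
  }
  # row index of the P atom of each residue, NA when absent
  p_row <- function(strand, resnos) {
    vapply(resnos, function(r) {
      w <- which(top$chain == strand & top$resno == r & top$atom == "P")
      if (length(w) == 1) w else NA_integer_
    }, integer(1))
  }
  p1 <- p_row(chain1, res1)                 # strand-1 P at bp index i
  p2 <- p_row(chain2, res2[n + 1 - seq_len(n)])  # strand-2 P at bp index j
  purrr::imap_dfr(frames, function(xyz, f) {
    width <- vapply(seq_len(n), function(i) {
      if (is.na(p1[i])) return(NA_real_)
      js <- i + registers
      js <- js[js >= 1 & js <= n]
      js <- js[!is.na(p2[js])]
      if (length(js) == 0) return(NA_real_)
      d <- sqrt(colSums((xyz[p1[i], ] - t(xyz[p2[js], , drop = FALSE]))^2))
      min(d) - offset_nm
    }, numeric(1))
    tibble::tibble(frame = f - 1L, time_ps = times[f],
                   step = seq_len(n), width_nm = width)
  })
}

#' @rdname minor_groove_width
#' @param profile Tibble returned by `minor_groove_width()`.
#' @export
groove_profile_mean <- function(profile) {
  dplyr::summarise(dplyr::group_by(profile, .data$step),
                   width_nm = mean(.data$width_nm),
                   .groups = "drop")
}

#' @rdname minor_groove_width
#' @param path Output TSV path.
#' @export
write_groove_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
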