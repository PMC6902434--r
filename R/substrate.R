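#' Extract the pair of reference windows flanking a join-point
#'
#' For each side of the junction the reference sequence around the break
#' is taken: `flank_window` bases before the break and `flank_window`
#' bases after it (300 bp total by default), oriented to read
#' coordinates (a substrate on the reference minus strand is
#' reverse-complemented before windowing).  The proximal window runs
#' across the proximal break (reference continuation past the junction);
#' the distal window runs across the distal break (reference preceding
#' the junction).  `anchor_col` marks the join-point: it is the number of
#' window columns on the 5' side of the break, identical for both
#' windows.  Windows that would extend past a contig edge are shortened
#' and flagged.
#'
#' @param j a `junction`
#' @param ref a `ref_store`
#' @param params a [signature_params()]
#' @return an object of class `"substrate_pair"` with fields
#'   `proximal_window`, `distal_window`, `anchor_col`, `window_radius`,
#'   `truncated`, `junction_id`.
#' @export
extract_substrate_pair <- function(j, ref, params = signature_params()) {
  r <- params$flank_window
  pw <- oriented_window(ref, j$proximal$chrom, proximal_break(j), r,
                        j$proximal$strand)
  dw <- oriented_window(ref, j$distal$chrom, distal_break(j), r,
                        j$distal$strand)
  if (pw$left != dw$left) {
    # unequal truncation on the 5' side: trim to the common anchor offset
    keep <- min(pw$left, dw$left)
    pw$seq <- substr(pw$seq, pw$left - keep + 1L, nchar(pw$seq))
    dw$seq <- substr(dw$seq, dw$left - keep + 1L, nchar(dw$seq))
    pw$left <- keep; dw$left <- keep
  }
  structure(list(
    proximal_window = pw$seq,
    distal_window = dw$seq,
    anchor_col = pw$left,
    window_radius = r,
    truncated = pw$truncated || dw$truncated,
    junction_id = j$junction_id
  ), class = "substrate_pair")
}

# oriented window of radius r around an oriented break coordinate; the
# break sits between columns `left` and `left + 1`
oriented_window <- function(ref, chrom, bpos, r, strand) {
  L <- ref_lengths(ref)[[chrom]]
  if (strand == "+") {
    start <- max(bpos - r, 0); end <- min(bpos + r, L)
    seq <- ref_fetch(ref, chrom, start, end, "+")
    left <- bpos - start
  } else {
    start <- max(bpos - r, 0); end <- min(bpos + r, L)
    seq <- ref_fetch(ref, chrom, start, end, "-")
    left <- end - bpos
  }
  list(seq = seq, left = as.integer(left),
       truncated = (bpos - r < 0) || (bpos + r > L))
}

#' Construct a substrate pair directly from two windows
#'
#' Mostly useful for testing detectors on synthetic windows.
#' @param proximal_window,distal_window window strings
#' @param anchor_col columns on the 5' side of the join-point
#' @param junction_id label
#' @return a `"substrate_pair"`
#' @export
substrate_pair <- function(proximal_window, distal_window, anchor_col,
                           junction_id = "jp") {
  stopifnot(anchor_col >= 0, anchor_col <= nchar(proximal_window),
            anchor_col <= nchar(distal_window))
  structure(list(proximal_window = toupper(proximal_window),
                 distal_window = toupper(distal_window),
                 anchor_col = as.integer(anchor_col),
                 window_radius = as.integer(
                   max(anchor_col, nchar(proximal_window) - anchor_col,
                       nchar(distal_window) - anchor_col)),
                 truncated = FALSE, junction_id = junction_id),
            class = "substrate_pair")
}

#' @export
print.substrate_pair <- function(x, ...) {
  cat(sprintf("Substrate pair %s: %d/%d bp windows, join-point after column %d%s\n",
              x$junction_id, nchar(x$proximal_window),
              nchar(x$distal_window), x$anchor_col,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
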