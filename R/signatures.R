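#' Detect microhomology at a join-point
#'
#' Microhomology is shared 100% nucleotide identity between the two
#' reference substrates at the join-point: the maximal contiguous run of
#' columns around the anchor where the proximal and distal windows are
#' identical.  N never matches anything.
#'
#' @param sp a `substrate_pair`
#' @return an object of class `"microhomology_call"`: `length` (bp),
#'   `sequence`, and the split `left`/`right` of the run around the
#'   anchor.
#' @export
detect_microhomology <- function(sp) {
  pc <- str_chars(sp$proximal_window)
  dc <- str_chars(sp$distal_window)
  a <- sp$anchor_col
  m <- min(length(pc), length(dc))
  eq <- pc[seq_len(m)] == dc[seq_len(m)] & pc[seq_len(m)] != "N" &
    dc[seq_len(m)] != "N"
  el <- 0L
  if (a >= 1L) {
    run <- rev(eq[seq_len(a)])
    bad <- which(!run)
    el <- if (length(bad)) bad[1L] - 1L else a
  }
  er <- 0L
  if (a < m) {
    run <- eq[(a + 1L):m]
    bad <- which(!run)
    er <- if (length(bad)) bad[1L] - 1L else m - a
  }
  len <- el + er
  structure(list(
    length = as.integer(len),
    sequence = if (len > 0) substr(sp$proximal_window, a - el + 1L, a + er)
               else "",
    left = as.integer(el), right = as.integer(er)
  ), class = "microhomology_call")
}

#' Detect microhomeology at a join-point
#'
#' Searches alignment segments anchored at the join-point (spanning or
#' abutting it, within `mhe_search_radius` columns on each side) for the
#' best segment satisfying the microhomeology definition: at least
#' `min_microhomeology_len` columns, identity at least
#' `microhomeology_identity_cutoff` (matched columns over all segment
#' columns, gap columns included, by default), every gap run at most
#' `max_gap_run` nt and accompanied by at least `min_post_gap_match`
#' matched columns moving away from the junction, segment delimited by
#' matched columns, and at least one non-matched column (a fully
#' identical block is a microhomology, not a microhomeology).  Among
#' qualifying segments the highest-scoring wins (match +1, mismatch -1,
#' gap open -2, gap column -0.5, the Needleman-Wunsch scheme); score
#' ties are broken by segment length, then identity, then by preferring
#' segments that span the join-point, then by the proximal-side (left)
#' extent.  Scoring (rather than raw length alone) keeps the reported
#' block anchored on real annealing evidence rather than mismatch
#' padding at exactly the identity cutoff.
#'
#' A qualifying segment must also score at least `mhe_min_gain` points
#' above the bare exact microhomology at the join-point: a microhomology
#' with a short imperfect fringe stays a microhomology, and only an
#' imperfect block adding real annealing evidence is called
#' microhomeology.
#'
#' The priming side is the substrate that matches the junction read
#' perfectly across the segment: since the read follows the proximal
#' window left of the anchor and the distal window right of it, imperfect
#' columns confined to the left flank imply proximal priming, confined to
#' the right flank distal priming, and on both flanks the side is
#' undetermined.
#'
#' @param sp a `substrate_pair`
#' @param mh a `microhomology_call` for the same pair (see
#'   [detect_microhomology()])
#' @param params a [signature_params()]
#' @return an object of class `"microhomeology_call"`.
#' @export
detect_microhomeology <- function(sp, mh = detect_microhomology(sp),
                                  params = signature_params()) {
  r <- params$mhe_search_radius
  a <- sp$anchor_col
  pc <- str_chars(sp$proximal_window)
  dc <- str_chars(sp$distal_window)
  la <- min(r, a)
  ra <- min(r, length(pc) - a, length(dc) - a)
  absent <- structure(list(
    present = FALSE, length = 0L, n_match = 0L, identity = NA_real_,
    gap_runs = integer(0), priming_side = NA_character_,
    contains_microhomology = FALSE, mh_position = "absent",
    aligned_prox = "", aligned_dist = "", left_cols = 0L, right_cols = 0L
  ), class = "microhomeology_call")
  if (la + ra < params$min_microhomeology_len) return(absent)

  toward <- identical(params$gap_followed_direction, "toward")
  p_left <- d_left <- p_right <- d_right <- ""
  if (la > 0L) {
    p_left <- paste(rev(pc[seq.int(a - la + 1L, a)]), collapse = "")
    d_left <- paste(rev(dc[seq.int(a - la + 1L, a)]), collapse = "")
  }
  if (ra > 0L) {
    p_right <- paste(pc[seq.int(a + 1L, a + ra)], collapse = "")
    d_right <- paste(dc[seq.int(a + 1L, a + ra)], collapse = "")
  }
  cap <- params$max_gap_runs
  dpL <- .mhe_dir_dp_cpp(p_left, d_left, la, params$max_gap_run,
                         params$min_post_gap_match, cap, toward)
  dpR <- .mhe_dir_dp_cpp(p_right, d_right, ra, params$max_gap_run,
                         params$min_post_gap_match, cap, toward)

  # entry for one direction with exactly `runs` gap runs; f constraint
  # applies to the junction-adjacent column; segments are scored with
  # the conventional nucleotide scheme (match +1, mismatch -1, gap open
  # -2, gap column -0.5; held in half-units)
  side_entry <- function(dp, c, first_match_only, runs) {
    if (c == 0L) {
      if (runs > 0L) return(NULL)
      return(list(matches = 0L, gaps = 0L, score2 = 0L, path = "",
                  f = NA_integer_))
    }
    row <- c + 1L
    col_of <- function(f) f + 2L * runs + 1L
    if (first_match_only) {
      mm <- dp$matches[row, col_of(1L)]
      if (is.na(mm)) return(NULL)
      return(list(matches = mm, gaps = dp$gapcols[row, col_of(1L)],
                  score2 = dp$score2[row, col_of(1L)],
                  path = dp$path[row, col_of(1L)], f = 1L))
    }
    s0 <- dp$score2[row, col_of(0L)]; s1 <- dp$score2[row, col_of(1L)]
    if (is.na(s0) && is.na(s1)) return(NULL)
    f <- if (is.na(s0) || (!is.na(s1) && s1 >= s0)) 1L else 0L
    list(matches = dp$matches[row, col_of(f)],
         gaps = dp$gapcols[row, col_of(f)],
         score2 = dp$score2[row, col_of(f)],
         path = dp$path[row, col_of(f)], f = f)
  }

  run_combos <- list()
  for (rl in 0:cap) for (rr in 0:(cap - rl))
    run_combos[[length(run_combos) + 1L]] <- c(rl, rr)

  best <- NULL
  for (n in seq.int(params$min_microhomeology_len, la + ra)) {
    for (cl in seq.int(max(0L, n - ra), min(n, la))) {
      cr <- n - cl
      for (rc in run_combos) {
        eL <- side_entry(dpL, cl, first_match_only = (cr == 0L), rc[1L])
        if (is.null(eL)) next
        eR <- side_entry(dpR, cr, first_match_only = (cl == 0L), rc[2L])
        if (is.null(eR)) next
        m <- eL$matches + eR$matches
        if (m >= n) next                     # no imperfection: microhomology
        sc <- eL$score2 + eR$score2
        # the imperfect block must beat the exact microhomology's own
        # score by mhe_min_gain net matches (score2 is in half-units)
        if (sc < 2L * mh$length + 2L * params$mhe_min_gain) next
        denom <- if (identical(params$identity_denominator, "nongap"))
          n - (eL$gaps + eR$gaps) else n
        if (denom <= 0) next
        idt <- m / denom
        if (idt < params$microhomeology_identity_cutoff) next
        cand <- list(n = n, m = m, sc = sc, identity = idt,
                     spanning = (cl > 0L && cr > 0L),
                     cl = cl, cr = cr, eL = eL, eR = eR)
        # highest score first, then longest, then identity, then
        # spanning the join-point, then the larger proximal-side extent
        better <- function(x, y) {
          if (x$sc != y$sc) return(x$sc > y$sc)
          if (x$n != y$n) return(x$n > y$n)
          # identity comparison on integers: x$m/x$n vs y$m/y$n
          if (x$m * y$n != y$m * x$n) return(x$m * y$n > y$m * x$n)
          if (x$spanning != y$spanning) return(x$spanning)
          x$cl > y$cl
        }
        if (is.null(best) || better(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best)) return(absent)

  # assemble the segment alignment, window left-to-right
  left_path <- rev(str_chars(best$eL$path))
  right_path <- str_chars(best$eR$path)
  build <- function(path, p_from, d_from) {
    ap <- character(0); ad <- character(0)
    i <- p_from; k <- d_from
    for (act in path) {
      if (act %in% c("M", "X", "D")) { ap <- c(ap, pc[i]); i <- i + 1L }
      else ap <- c(ap, "-")
      if (act %in% c("M", "X", "P")) { ad <- c(ad, dc[k]); k <- k + 1L }
      else ad <- c(ad, "-")
    }
    list(ap = ap, ad = ad)
  }
  # base extents per side from the paths themselves
  n_p <- function(path) sum(str_chars(path) %in% c("M", "X", "D"))
  n_d <- function(path) sum(str_chars(path) %in% c("M", "X", "P"))
  lP <- n_p(best$eL$path); lD <- n_d(best$eL$path)
  L <- build(left_path, a - lP + 1L, a - lD + 1L)
  R <- build(right_path, a + 1L, a + 1L)
  full_path <- c(left_path, right_path)
  aligned_prox <- paste(c(L$ap, R$ap), collapse = "")
  aligned_dist <- paste(c(L$ad, R$ad), collapse = "")
  gap_rle <- rle(full_path %in% c("P", "D"))
  gap_runs <- gap_rle$lengths[gap_rle$values]

  left_bad <- any(left_path != "M")
  right_bad <- any(right_path != "M")
  priming <- if (left_bad && right_bad) "undetermined"
             else if (left_bad) "proximal" else "distal"

  # position of the exact microhomology within the segment
  aL <- {
    runs <- rle(left_path == "M")
    if (length(runs$lengths) && runs$values[1L]) runs$lengths[1L] else 0L
  }
  aR <- {
    runs <- rle(right_path == "M")
    if (length(runs$lengths) && runs$values[1L]) runs$lengths[1L] else 0L
  }
  mh_real <- mh$length >= 1L
  contained <- mh_real && aL >= mh$left && aR >= mh$right
  position <- if (!contained) "absent"
    else if (mh$right == best$cr && mh$left < best$cl) "right_end"
    else if (mh$left == best$cl && mh$right < best$cr) "left_end"
    else "internal"

  structure(list(
    present = TRUE,
    length = as.integer(best$n),
    n_match = as.integer(best$m),
    identity = best$identity,
    gap_runs = as.integer(gap_runs),
    priming_side = priming,
    contains_microhomology = contained && mh$length >= 2L,
    mh_position = if (contained && mh$length >= 2L) position else "absent",
    aligned_prox = aligned_prox,
    aligned_dist = aligned_dist,
    left_cols = as.integer(best$cl),
    right_cols = as.integer(best$cr)
  ), class = "microhomeology_call")
}

#' @export
print.microhomology_call <- function(x, ...) {
  if (x$length == 0) cat("No microhomology (blunt-compatible)\n")
  else cat(sprintf("Microhomology: %d bp '%s' (%d left / %d right of the join-point)\n",
                   x$length, x$sequence, x$left, x$right))
  invisible(x)
}

#' @export
print.microhomeology_call <- function(x, ...) {
  if (!x$present) cat("No microhomeology\n")
  else {
    cat(sprintf("Microhomeology: %d columns, %d matches (identity %.2f), priming side %s\n",
                x$length, x$n_match, x$identity, x$priming_side))
    cat(" ", x$aligned_prox, "\n ", x$aligned_dist, "\n")
  }
  invisible(x)
}
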