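# Independent oracles used to cross-check the detectors and aligner.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

chars <- function(x) if (nchar(x)) strsplit(x, "")[[1]] else character(0)

# --- microhomology: plain two-direction extension with explicit loops ---
oracle_microhomology <- function(sp) {
  p <- chars(sp$proximal_window); d <- chars(sp$distal_window)
  a <- sp$anchor_col
  m <- min(length(p), length(d))
  same <- function(i) p[i] == d[i] && p[i] != "N" && d[i] != "N"
  el <- 0L
  i <- a
  while (i >= 1 && same(i)) { el <- el + 1L; i <- i - 1L }
  er <- 0L
  i <- a + 1L
  while (i <= m && same(i)) { er <- er + 1L; i <- i + 1L }
  el + er
}

# --- microhomeology: exhaustive segment-shape enumeration -----------------
#
# With the default constraints (at most one gap run of <= 2 nt, two
# matched columns following the gap moving away from the junction), every
# admissible segment half is "t1 diagonal columns, optionally a gap of
# g in one sequence, then t2 >= 2 diagonal columns".  All shapes are
# enumerated per flank and combined across the join-point, applying the
# qualification rules (>= 5 columns, >= 70% identity over all columns,
# at least one imperfection, score margin over the exact microhomology,
# terminal matches) and the score/length/identity selection order.
oracle_mhe_side <- function(p, d, C, mpg = 2L) {
  np <- length(p); nd <- length(d)
  score <- array(-Inf, dim = c(C + 1L, 2L, 2L))  # [c+1, f+1, r+1]
  match <- array(NA_integer_, dim = c(C + 1L, 2L, 2L))
  put <- function(c, f, r, sc, m) {
    if (sc > score[c + 1L, f + 1L, r + 1L]) {
      score[c + 1L, f + 1L, r + 1L] <<- sc
      match[c + 1L, f + 1L, r + 1L] <<- m
    }
  }
  nb <- min(np, nd)
  eq0 <- if (nb) p[seq_len(nb)] == d[seq_len(nb)] & p[seq_len(nb)] != "N" &
    d[seq_len(nb)] != "N" else logical(0)
  cum0 <- c(0L, cumsum(eq0))
  # gapless diagonal runs
  for (t in seq_len(min(C, nb))) {
    if (!eq0[t]) next                       # far end must be a match
    m <- cum0[t + 1L]
    put(t, as.integer(eq0[1L]), 0L, 4 * m - 2 * t, m)
  }
  # one gap run of length g in one sequence
  for (gap_in in c("P", "D")) {
    for (g in 1:2) {
      if (gap_in == "P") {
        nn <- min(np, nd - g)
        if (nn < 1) next
        eqg <- p[seq_len(nn)] == d[seq_len(nn) + g] &
          p[seq_len(nn)] != "N" & d[seq_len(nn) + g] != "N"
      } else {
        nn <- min(np - g, nd)
        if (nn < 1) next
        eqg <- p[seq_len(nn) + g] == d[seq_len(nn)] &
          p[seq_len(nn) + g] != "N" & d[seq_len(nn) + g] != "N"
      }
      cumg <- c(0L, cumsum(eqg))
      if (C < g + mpg) next
      for (t1 in 0:min(C - g - mpg, nb)) {
        f <- if (t1 == 0L) 0L else as.integer(eq0[1L])
        m1 <- cum0[t1 + 1L]
        t2max <- min(C - t1 - g, nn - t1)
        if (t2max < mpg) next
        for (t2 in mpg:t2max) {
          # the mpg columns after the gap must be matches
          if (!all(eqg[(t1 + 1L):(t1 + mpg)])) break
          if (!eqg[t1 + t2]) next           # far end must be a match
          m <- m1 + cumg[t1 + t2 + 1L] - cumg[t1 + 1L]
          c <- t1 + g + t2
          put(c, f, 1L, 4 * m - 2 * (t1 + t2) - (4 + g), m)
        }
      }
    }
  }
  list(score = score, match = match)
}

oracle_mhe <- function(sp, params = signature_params()) {
  stopifnot(params$max_gap_run == 2L, params$max_gap_runs == 1L,
            params$min_post_gap_match == 2L,
            identical(params$gap_followed_direction, "away"),
            identical(params$identity_denominator, "all_columns"))
  p <- chars(sp$proximal_window); d <- chars(sp$distal_window)
  a <- sp$anchor_col
  la <- min(params$mhe_search_radius, a)
  ra <- min(params$mhe_search_radius, length(p) - a, length(d) - a)
  mh_len <- oracle_microhomology(sp)
  L <- oracle_mhe_side(rev(p[seq_len(a)])[seq_len(la)],
                       rev(d[seq_len(a)])[seq_len(la)], la)
  R <- oracle_mhe_side(p[a + seq_len(ra)], d[a + seq_len(ra)], ra)
  get <- function(side, c, f_needed, r) {
    if (c == 0L) {
      if (r > 0L) return(NULL)
      return(c(sc = 0, m = 0))
    }
    fs <- if (f_needed) 2L else 1:2
    sc <- max(side$score[c + 1L, fs, r + 1L])
    if (!is.finite(sc)) return(NULL)
    idx <- fs[side$score[c + 1L, fs, r + 1L] == sc]
    c(sc = sc, m = max(side$match[c + 1L, idx, r + 1L], na.rm = TRUE))
  }
  best <- NULL
  for (n in seq.int(params$min_microhomeology_len, la + ra)) {
    for (cl in seq.int(max(0L, n - ra), min(n, la))) {
      cr <- n - cl
      for (rl in 0:1) for (rr in 0:(1 - rl)) {
        eL <- get(L, cl, f_needed = (cr == 0L), rl)
        if (is.null(eL)) next
        eR <- get(R, cr, f_needed = (cl == 0L), rr)
        if (is.null(eR)) next
        m <- eL[["m"]] + eR[["m"]]
        if (m >= n) next
        sc <- eL[["sc"]] + eR[["sc"]]
        if (sc < 2 * mh_len + 2 * params$mhe_min_gain) next
        if (m / n < params$microhomeology_identity_cutoff) next
        cand <- c(sc = sc, n = n, m = m)
        if (is.null(best) || cand[["sc"]] > best[["sc"]] ||
            (cand[["sc"]] == best[["sc"]] && cand[["n"]] > best[["n"]]) ||
            (cand[["sc"]] == best[["sc"]] && cand[["n"]] == best[["n"]] &&
               cand[["m"]] > best[["m"]]))
          best <- cand
      }
    }
  }
  if (is.null(best)) list(present = FALSE, length = 0L, n_match = 0L)
  else list(present = TRUE, length = unname(best[["n"]]),
            n_match = unname(best[["m"]]))
}

# --- brute-force validation of the segment oracle on tiny windows --------
# Full recursion over away-order action strings under the written rules.
dfs_mhe_side <- function(p, d, C, mpg = 2L) {
  results <- list()
  recur <- function(i, j, cols, m, sc, state, gap_used, first_m, gr) {
    # state: "clean" (last col match), "cleanx", "owe1", "gP1","gP2","gD1","gD2"
    if (cols > 0 && state == "clean")
      results[[length(results) + 1L]] <<-
        c(c = cols, f = first_m, r = gap_used, sc = sc, m = m)
    if (cols == C) return()
    can_m <- i < length(p) && j < length(d) && p[i + 1L] == d[j + 1L] &&
      p[i + 1L] != "N"
    can_x <- i < length(p) && j < length(d) && !can_m
    fm <- if (cols == 0L) 1L else first_m
    fo <- if (cols == 0L) 0L else first_m
    if (state %in% c("clean", "cleanx")) {
      if (can_m) recur(i + 1L, j + 1L, cols + 1L, m + 1L, sc + 2, "clean",
                       gap_used, fm, gr)
      if (can_x) recur(i + 1L, j + 1L, cols + 1L, m, sc - 2, "cleanx",
                       gap_used, fo, gr)
      if (!gap_used && j < length(d))
        recur(i, j + 1L, cols + 1L, m, sc - 5, "gP1", 1L, fo, gr)
      if (!gap_used && i < length(p))
        recur(i + 1L, j, cols + 1L, m, sc - 5, "gD1", 1L, fo, gr)
    } else if (state == "gP1") {
      if (j < length(d)) recur(i, j + 1L, cols + 1L, m, sc - 1, "gP2",
                               gap_used, first_m, gr)
      if (can_m) recur(i + 1L, j + 1L, cols + 1L, m + 1L, sc + 2, "owe1",
                       gap_used, first_m, gr)
    } else if (state == "gP2") {
      if (can_m) recur(i + 1L, j + 1L, cols + 1L, m + 1L, sc + 2, "owe1",
                       gap_used, first_m, gr)
    } else if (state == "gD1") {
      if (i < length(p)) recur(i + 1L, j, cols + 1L, m, sc - 1, "gD2",
                               gap_used, first_m, gr)
      if (can_m) recur(i + 1L, j + 1L, cols + 1L, m + 1L, sc + 2, "owe1",
                       gap_used, first_m, gr)
    } else if (state == "gD2") {
      if (can_m) recur(i + 1L, j + 1L, cols + 1L, m + 1L, sc + 2, "owe1",
                       gap_used, first_m, gr)
    } else if (state == "owe1") {
      if (can_m) recur(i + 1L, j + 1L, cols + 1L, m + 1L, sc + 2, "clean",
                       gap_used, first_m, gr)
    }
  }
  recur(0L, 0L, 0L, 0L, 0, "clean", 0L, 0L, 0L)
  results
}

dfs_mhe <- function(sp, params = signature_params()) {
  p <- chars(sp$proximal_window); d <- chars(sp$distal_window)
  a <- sp$anchor_col
  la <- min(params$mhe_search_radius, a)
  ra <- min(params$mhe_search_radius, length(p) - a, length(d) - a)
  mh_len <- oracle_microhomology(sp)
  segsL <- dfs_mhe_side(rev(p[seq_len(a)])[seq_len(la)],
                        rev(d[seq_len(a)])[seq_len(la)], la)
  segsR <- dfs_mhe_side(p[a + seq_len(ra)], d[a + seq_len(ra)], ra)
  empty <- c(c = 0, f = NA, r = 0, sc = 0, m = 0)
  best <- NULL
  for (l in c(list(empty), segsL)) for (r in c(list(empty), segsR)) {
    if (l[["r"]] + r[["r"]] > 1) next
    n <- l[["c"]] + r[["c"]]
    if (n < params$min_microhomeology_len) next
    if (l[["c"]] == 0 && !is.na(r[["f"]]) && r[["f"]] != 1) next
    if (r[["c"]] == 0 && !is.na(l[["f"]]) && l[["f"]] != 1) next
    m <- l[["m"]] + r[["m"]]
    if (m >= n) next
    sc <- l[["sc"]] + r[["sc"]]
    if (sc < 2 * mh_len + 2 * params$mhe_min_gain) next
    if (m / n < params$microhomeology_identity_cutoff) next
    cand <- c(sc = sc, n = n, m = m)
    if (is.null(best) || cand[["sc"]] > best[["sc"]] ||
        (cand[["sc"]] == best[["sc"]] && cand[["n"]] > best[["n"]]) ||
        (cand[["sc"]] == best[["sc"]] && cand[["n"]] == best[["n"]] &&
           cand[["m"]] > best[["m"]]))
      best <- cand
  }
  if (is.null(best)) list(present = FALSE, length = 0L, n_match = 0L)
  else list(present = TRUE, length = unname(best[["n"]]),
            n_match = unname(best[["m"]]))
}

# --- Needleman-Wunsch score oracle (Biostrings) --------------------------
oracle_nw_score <- function(a, b, params = signature_params()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$nw_match,
                                                  mismatch = params$nw_mismatch,
                                                  baseOnly = TRUE)
  BiocGenerics::score(Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = params$nw_gap_open, gapExtension = params$nw_gap_ext))
}
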