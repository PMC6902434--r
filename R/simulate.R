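#' Simulate a random reference sequence
#'
#' Generates i.i.d. bases at a target GC content.  Deterministic for a
#' fixed seed; the base composition converges on the requested GC (for
#' sequences of 100 kb or more it is within about two percentage
#' points).
#'
#' @param length sequence length in bp (at least 1000)
#' @param gc target GC fraction
#' @param seed integer seed
#' @param chrom sequence name
#' @return a `ref_store` with one sequence
#' @export
simulate_reference <- function(length, gc = 0.41, seed = 1L,
                               chrom = "chrS") {
  if (length < 1000)
    stop("reference length must be at least 1000 bp")
  with_seed(seed, {
    s <- rand_bases(length, gc)
    ref_store(stats::setNames(paste(s, collapse = ""), chrom))
  })
}

rand_bases <- function(n, gc = 0.41) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# replace bases of a character scalar at 0-based [start, start + n)
splice_str <- function(s, start, repl) {
  n <- nchar(repl)
  paste0(substr(s, 1L, start), repl, substr(s, start + n + 1L, nchar(s)))
}

# largest-remainder apportionment of n among weights
apportion <- function(weights, n) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(q - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  as.integer(base)
}

# -------------------------------------------------------------------------
# window-level signature planting
#
# Builds a fresh pair of substrate windows (oriented base vectors of
# radius `canvas` around the break) carrying exactly the requested
# join-point signature, verified with the package's own detectors;
# flanks creating accidental signatures larger than the planted one are
# rejected and resampled.  The caller writes the windows into the
# reference.

plant_windows <- function(category, params = signature_params(),
                          mh_len = NULL, mhe_len = NULL,
                          mhe_identity = NULL, mhe_variant = NULL,
                          insertion_len = NULL, templated = NA,
                          canvas = 35L, max_attempts = 80L) {
  r <- canvas
  a <- r  # anchor column inside the canvas windows
  truth <- list(planted_category = category, planted_mh_len = 0L,
                planted_mhe_len = 0L, planted_mhe_identity = NA_real_,
                planted_insertion_len = 0L, planted_priming = NA_character_,
                templated = templated)
  # fixed draws so every attempt re-verifies the same requested signature
  if (category == "microhomology" && is.null(mh_len))
    mh_len <- sample(2:9, 1L)
  if (category == "microhomeology") {
    if (is.null(mhe_len)) mhe_len <- sample(7:14, 1L)
    if (is.null(mhe_identity)) mhe_identity <- stats::runif(1, 0.70, 0.90)
    if (is.null(mhe_variant))
      mhe_variant <- sample(c("pure_left", "pure_right", "with_mh_left",
                              "with_mh_right", "internal"), 1L,
                            prob = c(0.3, 0.25, 0.15, 0.15, 0.15))
  }
  if (category == "insertion" && is.null(insertion_len)) {
    small <- is.na(templated) || stats::runif(1) < 0.85
    insertion_len <- if (small) sample(1:params$small_insertion_max, 1L)
                     else sample((params$small_insertion_max + 1L):40L, 1L)
  }
  if (category == "insertion" && is.na(templated))
    templated <- stats::runif(1) < 0.5

  for (attempt in seq_len(max_attempts)) {
    P <- rand_bases(2L * r)
    D <- rand_bases(2L * r)
    ins <- ""
    set_match <- function(offs) D[a + 1L + offs] <<- P[a + 1L + offs]
    set_mismatch <- function(offs) {
      for (o in offs)
        D[a + 1L + o] <<- sample(setdiff(DNA_BASES, P[a + 1L + o]), 1L)
    }
    ok_spec <- TRUE
    if (category == "blunt") {
      set_mismatch(c(-1L, 0L))
    } else if (category == "one_bp_match") {
      if (stats::runif(1) < 0.5) {          # single shared base 5' of the join
        set_match(-1L); set_mismatch(c(-2L, 0L))
      } else {
        set_match(0L); set_mismatch(c(-1L, 1L))
      }
      truth$planted_mh_len <- 1L
    } else if (category == "microhomology") {
      el <- sample.int(mh_len + 1L, 1L) - 1L
      er <- mh_len - el
      offs <- setdiff(seq.int(-el, er - 1L), integer(0))
      set_match(offs)
      set_mismatch(c(-el - 1L, er))
      truth$planted_mh_len <- as.integer(mh_len)
    } else if (category == "microhomeology") {
      L <- mhe_len
      k <- max(1L, min(as.integer(floor((1 - mhe_identity) * L + 0.5)),
                       as.integer(floor(0.3 * L))))
      # keep the realized identity at or below 0.90 after discretisation
      k <- max(k, as.integer(ceiling(L / 10 - 1e-9)))
      # demote variants that cannot satisfy the score-margin rule at
      # this length/mismatch combination
      v <- mhe_variant
      if (v == "internal" && (k < 2L || L < 2L * k + 4L))
        v <- "pure_left"
      if (v %in% c("with_mh_left", "with_mh_right") &&
          min(4L, L - 2L * k - 2L) < 2L)
        v <- if (v == "with_mh_left") "pure_left" else "pure_right"
      plan <- mhe_layout(L, k, v)
      if (is.null(plan)) { ok_spec <- FALSE; break }
      set_match(plan$match_offs)
      set_mismatch(plan$mismatch_offs)
      truth$planted_mhe_len <- as.integer(L)
      truth$planted_mhe_identity <- (L - k) / L
      truth$planted_mh_len <- plan$mh_len
      truth$planted_priming <- plan$priming
    } else if (category == "insertion") {
      set_mismatch(c(-1L, 0L))
      ins <- rand_bases(insertion_len)
      # the insertion must not extend either exact mapping; for a 1-bp
      # insertion both constraints bind the same base
      end_bad <- if (insertion_len == 1L) c(P[a + 1L], D[a]) else P[a + 1L]
      if (ins[1L] %in% end_bad)
        ins[1L] <- sample(setdiff(DNA_BASES, end_bad), 1L)
      if (ins[insertion_len] == D[a])
        ins[insertion_len] <- sample(setdiff(DNA_BASES, c(D[a], end_bad[-1L])), 1L)
      truth$planted_insertion_len <- as.integer(insertion_len)
    } else {
      stop("plant_windows does not handle category '", category, "'")
    }
    if (!ok_spec) break

    sp <- substrate_pair(paste(P, collapse = ""), paste(D, collapse = ""), a)
    mh <- detect_microhomology(sp)
    mhe <- detect_microhomeology(sp, mh, params)
    good <- switch(category,
      blunt = mh$length == 0L && !mhe$present,
      one_bp_match = mh$length == 1L && !mhe$present,
      microhomology = mh$length == mh_len && !mhe$present,
      microhomeology = mhe$present && mhe$length == truth$planted_mhe_len &&
        mhe$n_match == truth$planted_mhe_len -
          round((1 - truth$planted_mhe_identity) * truth$planted_mhe_len) &&
        identical(mhe$priming_side, truth$planted_priming),
      insertion = TRUE)
    if (good)
      return(list(P = P, D = D, insertion = paste(ins, collapse = ""),
                  truth = truth))
  }
  stop(sprintf(
    "could not plant a '%s' signature after %d attempts (constraint: %s)",
    category, max_attempts,
    if (category == "microhomeology")
      sprintf("len %d identity %.2f variant %s", mhe_len, mhe_identity,
              mhe_variant) else "flank uniqueness"))
}

# offset layout (relative to the anchor; -1 = base just 5' of the break)
# for a planted microhomeology of L columns with k mismatched columns
mhe_layout <- function(L, k, variant) {
  pick <- function(pool, n) if (n == 0L) integer(0) else
    if (length(pool) < n) NULL else sample(pool, n)
  if (variant %in% c("pure_left", "with_mh_left")) {
    offs <- seq.int(-L, -1L)                       # segment left of the join
    forced_mm <- if (variant == "pure_left") -2L else integer(0)
    mh_m <- 0L
    if (variant == "with_mh_left") {
      top <- min(4L, L - 2L * k - 2L)
      if (top < 2L) return(NULL)
      mh_m <- if (top == 2L) 2L else sample(2:top, 1L)
      forced_mm <- -(mh_m + 1L)
    }
    interior <- setdiff(seq.int(-(L - 1L), -2L), forced_mm)
    if (variant == "with_mh_left")
      interior <- setdiff(interior, seq.int(-mh_m, -2L))
    extra <- pick(interior, k - length(forced_mm))
    if (is.null(extra)) return(NULL)
    mm <- c(forced_mm, extra)
    list(match_offs = setdiff(offs, mm), mismatch_offs = c(mm, 0L),
         mh_len = if (variant == "with_mh_left") mh_m else 1L,
         priming = "proximal")
  } else if (variant %in% c("pure_right", "with_mh_right")) {
    offs <- seq.int(0L, L - 1L)
    forced_mm <- if (variant == "pure_right") 1L else integer(0)
    mh_m <- 0L
    if (variant == "with_mh_right") {
      top <- min(4L, L - 2L * k - 2L)
      if (top < 2L) return(NULL)
      mh_m <- if (top == 2L) 2L else sample(2:top, 1L)
      forced_mm <- mh_m
    }
    interior <- setdiff(seq.int(1L, L - 2L), forced_mm)
    if (variant == "with_mh_right")
      interior <- setdiff(interior, seq.int(1L, mh_m - 1L))
    extra <- pick(interior, k - length(forced_mm))
    if (is.null(extra)) return(NULL)
    mm <- c(forced_mm, extra)
    list(match_offs = setdiff(offs, mm), mismatch_offs = c(mm, -1L),
         mh_len = if (variant == "with_mh_right") mh_m else 1L,
         priming = "distal")
  } else {                                         # internal: spans the join
    if (k < 2L || L < 2L * k + 4L) return(NULL)
    l <- as.integer(ceiling(L / 2)); rr <- L - l
    if (l < 3L || rr < 3L) return(NULL)
    forced <- c(-2L, 1L)                           # one imperfection per side
    interior <- setdiff(c(seq.int(-(l - 1L), -2L), seq.int(1L, rr - 2L)),
                        forced)
    extra <- pick(interior, k - 2L)
    if (is.null(extra)) return(NULL)
    mm <- c(forced, extra)
    # offsets -1 and 0 stay matched: a 2-bp microhomology sits inside
    list(match_offs = setdiff(seq.int(-l, rr - 1L), mm), mismatch_offs = mm,
         mh_len = 2L, priming = "undetermined")
  }
}

# write an oriented window (base vector, anchor at `canvas`) into a plain
# character chromosome string around an oriented break position
write_window_str <- function(s, bpos, strand, win) {
  r <- length(win) %/% 2L
  w <- paste(win, collapse = "")
  if (strand == "+") splice_str(s, bpos - r, w)
  else splice_str(s, bpos - r, revcomp_chr(w))
}

#' Plant a single junction with a known signature
#'
#' Picks two loci on the reference, writes substrate windows carrying
#' exactly the requested join-point signature (flanks that would create
#' an accidental signature exceeding the planted one are rejected and
#' resampled), and assembles the junction read following the proximal
#' substrate up to the break and the distal substrate after it.  For
#' microhomeology the distal window copies a segment of the proximal
#' window with exactly the number of mismatches implied by the requested
#' identity; the realized (discretised) identity is recorded in the
#' truth record.
#'
#' @param ref a `ref_store`
#' @param spec a list with `category` (one of the classifier's
#'   categories) and optional `mh_len`, `mhe_len` (5-30),
#'   `mhe_identity` (0.70-0.95), `mhe_variant`, `insertion_len`,
#'   `templated`
#' @param seed integer seed
#' @param chrom chromosome to plant on (default: first)
#' @param params a [signature_params()]
#' @return a list with `junction`, `truth` (one-row data.frame),
#'   `annotations` (repeat rows for chimeric categories, else empty) and
#'   `ref` (the edited store)
#' @export
plant_junction <- function(ref, spec, seed = NULL,
                           chrom = names(ref$seqs)[1L],
                           params = signature_params()) {
  stopifnot(is.list(spec), !is.null(spec$category))
  if (!spec$category %in% joinpoint_categories)
    stop("unknown category '", spec$category, "'; supported: ",
         paste(joinpoint_categories, collapse = ", "))
  if (!is.null(spec$mhe_identity) &&
      (spec$mhe_identity < 0.70 || spec$mhe_identity > 0.95))
    stop("requested microhomeology identity must be in [0.70, 0.95]")
  if (!is.null(spec$mhe_len) && (spec$mhe_len < 5 || spec$mhe_len > 30))
    stop("requested microhomeology length must be in [5, 30]")
  with_seed(seed, {
    L <- ref_lengths(ref)[[chrom]]
    flank <- params$flank_window
    margin <- flank + 60
    if (L < 2 * margin + 700)
      stop("chromosome too short to plant a junction")
    repeat {
      a <- sample.int(L - 2 * margin, 1L) + margin
      b <- sample.int(L - 2 * margin, 1L) + margin
      if (abs(a - b) >= 2 * flank + 100) break
    }
    res <- plant_on_string(as.character(ref$seqs[[chrom]]), chrom, a, b,
                           spec, params)
    ref$seqs[[chrom]] <- Biostrings::DNAString(res$s)
    jid <- if (!is.null(spec$junction_id)) spec$junction_id else "planted_jct"
    j <- junction(jid, if (!is.null(spec$individual_id))
                    spec$individual_id else "sim", res$read,
                  res$proximal, res$distal, ref = ref, params = params)
    truth <- data.frame(junction_id = jid,
                        individual_id = j$individual_id,
                        structure_label = NA_character_,
                        res$truth, stringsAsFactors = FALSE)
    list(junction = j, truth = truth, annotations = res$annotations,
         ref = ref)
  })
}

# core planting on a character chromosome: breaks at + strand positions
# a (proximal, sequence ends there) and b (distal, sequence starts
# there); returns the edited string, the read and interval pair
plant_on_string <- function(s, chrom, a, b, spec, params,
                            prox_strand = "+", dist_strand = "+",
                            build_read = TRUE) {
  flank <- params$flank_window
  annotations <- NULL
  chim <- c(alu_alu_chimera = "Alu", line_line_chimera = "LINE",
            paralogous_repeat_other = "self_chain")
  if (spec$category %in% names(chim)) {
    # paralogous elements: the distal region is a mutated copy of the
    # proximal region (about 90% identity)
    stopifnot(prox_strand == "+", dist_strand == "+")
    src <- str_chars(substr(s, a - flank + 1L, a + flank))
    mut <- stats::runif(length(src)) < 0.1
    cpy <- src
    cpy[mut] <- vapply(src[mut], function(x)
      sample(setdiff(DNA_BASES, x), 1L), character(1))
    inverted <- isTRUE(spec$inverted)
    s <- splice_str(s, b - flank, paste(cpy, collapse = ""))
    kl <- unname(chim[spec$category])
    nm <- switch(kl, Alu = c("AluSx1", "AluY"), LINE = c("L1PA5", "L1PA3"),
                 self_chain = c("selfchain_a", "selfchain_b"))
    annotations <- rbind(
      repeat_annotation(chrom, a - flank, a + flank, kl, nm[1L],
                        sub("[0-9]+$", "", nm[1L]), "+"),
      repeat_annotation(chrom, b - flank, b + flank, kl, nm[2L],
                        sub("[0-9]+$", "", nm[2L]),
                        if (inverted) "-" else "+"))
    truth <- list(planted_category = spec$category, planted_mh_len = NA_integer_,
                  planted_mhe_len = NA_integer_,
                  planted_mhe_identity = NA_real_,
                  planted_insertion_len = 0L,
                  planted_priming = NA_character_, templated = NA)
    ins <- ""
  } else {
    pw <- plant_windows(spec$category, params,
                        mh_len = spec$mh_len, mhe_len = spec$mhe_len,
                        mhe_identity = spec$mhe_identity,
                        mhe_variant = spec$mhe_variant,
                        insertion_len = spec$insertion_len,
                        templated = if (is.null(spec$templated)) NA
                                    else spec$templated)
    s <- write_window_str(s, a, prox_strand, pw$P)
    s <- write_window_str(s, b, dist_strand, pw$D)
    ins <- pw$insertion
    if (nzchar(ins) && isTRUE(pw$truth$templated) &&
        prox_strand == "+" && dist_strand == "+") {
      # templated insertion: copy from a third locus when one fits
      li <- nchar(ins)
      lo <- min(a, b) - flank - 400L
      if (lo > li + 10L) {
        org <- sample.int(lo - li, 1L)
        tpl <- str_chars(substr(s, org + 1L, org + li))
        pa <- str_chars(substr(s, a + 1L, a + 1L))
        db <- str_chars(substr(s, b, b))
        if (tpl[1L] != pa && tpl[li] != db) ins <- paste(tpl, collapse = "")
      }
    }
    truth <- pw$truth
  }
  prox <- gi(chrom,
             if (prox_strand == "+") a - flank else a,
             if (prox_strand == "+") a else a + flank, prox_strand)
  dist <- gi(chrom,
             if (dist_strand == "+") b else b - flank,
             if (dist_strand == "+") b + flank else b, dist_strand)
  read <- NULL
  if (build_read) {
    sref <- ref_store(stats::setNames(s, chrom))
    read <- paste0(ref_fetch_interval(sref, prox), ins,
                   ref_fetch_interval(sref, dist))
  }
  list(s = s, read = read, insertion = ins, proximal = prox, distal = dist,
       truth = truth, annotations = annotations)
}

# -------------------------------------------------------------------------
# multi-segment rearrangement structures

rearrangement_patterns <- c("DUP", "DUP-NML-DUP", "DUP-TRP-DUP",
                            "DUP-NML-DEL", "DUP-QUAD-TRP",
                            "DUP-NML-DUP-NML-DUP")

samp_int <- function(lo, hi) {
  if (hi - lo < 1) return(NA_integer_)
  as.integer(lo) + sample.int(as.integer(hi - lo), 1L)
}

# sample the boundary set of a pattern; NULL on an infeasible draw
sample_layout <- function(pattern, L, cons, annot, reserved, minseg = 600L,
                          sep = 100L, margin = 1500L) {
  prox <- cons$prox_range %||% c(margin, floor(0.45 * L))
  distr <- cons$dist_range %||% c(floor(0.5 * L), L - margin)
  lcr <- function(nm) {
    if (is.null(annot)) return(NULL)
    x <- annot[annot$name == nm, , drop = FALSE]
    if (nrow(x)) x[1L, ] else NULL
  }
  a1a <- lcr("LCRA1a"); a1b <- lcr("LCRA1b")
  last <- if (!is.null(cons$dist_in))
    samp_int(cons$dist_in$start + 10L, cons$dist_in$end - 10L)
  else samp_int(distr[1L], distr[2L])
  if (is.na(last)) return(NULL)
  nb <- switch(pattern, DUP = 2L, `DUP-NML-DUP` = 4L, `DUP-TRP-DUP` = 4L,
               `DUP-NML-DEL` = 4L, `DUP-QUAD-TRP` = 4L,
               `DUP-NML-DUP-NML-DUP` = 6L)
  s1 <- samp_int(prox[1L], min(prox[2L], last - (nb - 1L) * minseg))
  if (is.na(s1)) return(NULL)
  bs <- NULL
  if (pattern == "DUP-NML-DUP" && isTRUE(cons$h2) && !is.null(a1a) &&
      !is.null(a1b)) {
    # proximal dup ends in LCRA1a; the copy-neutral region and the
    # distal dup stay within the LCRA1a..LCRA1b span
    e1 <- samp_int(a1a$start + 10L, a1a$end - 10L)
    if (is.na(e1)) return(NULL)
    s2 <- samp_int(a1b$start + 10L, a1b$end - minseg - 20L)
    if (is.na(s2)) return(NULL)
    e2 <- samp_int(s2 + minseg, a1b$end - 10L)
    if (is.na(e2) || s1 >= e1 - minseg) return(NULL)
    bs <- c(s1, e1, s2, e2)
  } else if (pattern == "DUP-TRP-DUP" && isTRUE(cons$lcr_jct) &&
             !is.null(a1a) && !is.null(a1b)) {
    s3 <- samp_int(a1a$start + 10L, a1a$end - 10L)
    s4 <- samp_int(a1b$start + 10L, a1b$end - 10L)
    if (is.na(s3) || is.na(s4)) return(NULL)
    s2 <- samp_int(s1 + minseg, s3 - minseg)
    if (is.na(s2)) return(NULL)
    bs <- c(s1, s2, s3, s4)
  } else if (nb == 2L) {
    bs <- c(s1, last)
  } else {
    hi <- min(last - minseg, cons$mid_max %||% (last - minseg))
    mid <- sort(vapply(seq_len(nb - 2L), function(i)
      samp_int(s1 + minseg, hi), integer(1)))
    if (anyNA(mid)) return(NULL)
    bs <- c(s1, mid, last)
  }
  if (any(diff(bs) < minseg)) return(NULL)
  if (any(bs < margin | bs > L - margin)) return(NULL)
  if (length(reserved) && min(abs(outer(bs, reserved, "-"))) < sep)
    return(NULL)
  bs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# replication plan (ordered oriented pieces of the derived haplotype) and
# the copy-state profile it implies
plan_pieces <- function(pattern, bs, L) {
  p <- function(st, en, strand = "+") list(start = st, end = en,
                                           strand = strand)
  switch(pattern,
    DUP = list(p(0, bs[2L]), p(bs[1L], L)),
    `DUP-NML-DUP` = list(p(0, bs[4L]), p(bs[1L], bs[2L]), p(bs[3L], L)),
    `DUP-TRP-DUP` = list(p(0, bs[4L]), p(bs[2L], bs[3L], "-"),
                         p(bs[1L], L)),
    `DUP-NML-DEL` = list(p(0, bs[2L]), p(bs[1L], bs[3L]), p(bs[4L], L)),
    `DUP-QUAD-TRP` = list(p(0, bs[4L]), p(bs[2L], bs[4L]),
                          p(bs[2L], bs[4L]), p(bs[2L], bs[3L]),
                          p(bs[1L], bs[2L]), p(bs[4L], L)),
    `DUP-NML-DUP-NML-DUP` = list(p(0, bs[6L]), p(bs[1L], bs[2L]),
                                 p(bs[3L], bs[4L]), p(bs[5L], L)),
    stop("unknown pattern '", pattern, "'; supported: ",
         paste(rearrangement_patterns, collapse = ", ")))
}

plan_coverage <- function(pieces, chrom, L, individual_id) {
  pos <- sort(unique(c(0, L, unlist(lapply(pieces, function(x)
    c(x$start, x$end))))))
  cov <- vapply(seq_len(length(pos) - 1L), function(i)
    sum(vapply(pieces, function(x)
      x$start <= pos[i] && pos[i + 1L] <= x$end, logical(1))), integer(1))
  if (any(cov > 4L))
    stop("copy state above QUAD is not supported (max amplification 4)")
  segs <- data.frame(chrom = chrom, start = pos[-length(pos)],
                     end = pos[-1L],
                     state = copy_states[cov + 1L],
                     stringsAsFactors = FALSE)
  cnv_profile(individual_id, segs)
}

plan_adjacencies <- function(pieces) {
  adj <- list()
  for (i in seq_len(length(pieces) - 1L)) {
    a <- pieces[[i]]; b <- pieces[[i + 1L]]
    pb <- if (a$strand == "+") a$end else a$start
    db <- if (b$strand == "+") b$start else b$end
    key <- paste(pb, a$strand, db, b$strand)
    if (!key %in% vapply(adj, `[[`, character(1), "key"))
      adj[[length(adj) + 1L]] <- list(prox_break = pb,
                                      prox_strand = a$strand,
                                      dist_break = db,
                                      dist_strand = b$strand, key = key)
  }
  adj
}

# core generator on a plain chromosome string; the caller controls RNG
sim_rearr_core <- function(s, chrom, pattern, individual_id, annot, cons,
                           categories, reserved, params,
                           drop_junctions = integer(0),
                           build_reads = TRUE) {
  L <- nchar(s)
  bs <- NULL
  for (attempt in seq_len(2000L)) {
    bs <- sample_layout(pattern, L, cons, annot, reserved)
    if (!is.null(bs)) break
  }
  if (is.null(bs))
    stop("could not place pattern ", pattern,
         " (constraints unsatisfiable after 2000 layout attempts)")
  pieces <- plan_pieces(pattern, bs, L)
  profile <- plan_coverage(pieces, chrom, L, individual_id)
  adj <- plan_adjacencies(pieces)

  # forced LCR-mediated adjacencies (chimeric LCR element by NAHR)
  forced <- rep(NA_character_, length(adj))
  if (pattern == "DUP-TRP-DUP" && isTRUE(cons$lcr_jct) && !is.null(annot))
    forced[1L] <- "paralogous_repeat_other"
  if (pattern == "DUP-NML-DUP" && isTRUE(cons$h2) && !is.null(annot)) {
    hit <- vapply(adj, function(x)
      x$prox_break == bs[2L] && x$dist_break == bs[3L], logical(1))
    forced[hit] <- "paralogous_repeat_other"
  }

  # an adjacency is plantable when the distal side is on the plus strand
  # and its breakpoints are not shared with another junction
  allb <- unlist(lapply(adj, function(x) c(x$prox_break, x$dist_break)))
  plantable <- vapply(seq_along(adj), function(i) {
    x <- adj[[i]]
    is.na(forced[i]) && x$dist_strand == "+" &&
      sum(allb == x$prox_break) == 1L && sum(allb == x$dist_break) == 1L
  }, logical(1))

  used <- 0L
  jrows <- list()
  flank <- params$flank_window
  for (i in seq_along(adj)) {
    x <- adj[[i]]
    jid <- sprintf("%s_jct%d", individual_id, i)
    if (plantable[i]) {
      used <- used + 1L
      cat_i <- if (used <= length(categories)) categories[used] else
        sample(c("blunt", "one_bp_match", "microhomology",
                 "microhomeology", "insertion"), 1L)
      res <- plant_on_string(s, chrom, x$prox_break, x$dist_break,
                             list(category = cat_i), params,
                             prox_strand = x$prox_strand,
                             dist_strand = x$dist_strand,
                             build_read = FALSE)
      s <- res$s
      jrows[[length(jrows) + 1L]] <-
        c(list(junction_id = jid, insertion = res$insertion,
               proximal = res$proximal, distal = res$distal), res$truth)
    } else {
      prox <- gi(chrom,
                 if (x$prox_strand == "+") x$prox_break - flank else x$prox_break,
                 if (x$prox_strand == "+") x$prox_break else x$prox_break + flank,
                 x$prox_strand)
      dist <- gi(chrom,
                 if (x$dist_strand == "+") x$dist_break else x$dist_break - flank,
                 if (x$dist_strand == "+") x$dist_break + flank else x$dist_break,
                 x$dist_strand)
      jrows[[length(jrows) + 1L]] <-
        c(list(junction_id = jid, insertion = "", proximal = prox,
               distal = dist),
          list(planted_category = if (is.na(forced[i])) "unplanted"
                                  else forced[i],
               planted_mh_len = NA_integer_, planted_mhe_len = NA_integer_,
               planted_mhe_identity = NA_real_, planted_insertion_len = 0L,
               planted_priming = NA_character_, templated = NA))
    }
  }
  # reads are assembled from the final edited sequence so that every
  # junction read is consistent with the reference as written; a cohort
  # caller defers this until all individuals' edits are in
  if (build_reads) jrows <- assemble_reads(jrows, s, chrom)
  unresolved <- NULL
  if (length(drop_junctions)) {
    ids <- vapply(jrows, `[[`, character(1), "junction_id")
    drop_ids <- sprintf("%s_jct%d", individual_id, drop_junctions)
    unresolved <- do.call(rbind, lapply(jrows[ids %in% drop_ids], function(r)
      data.frame(individual_id = individual_id,
                 prox_break = r$proximal$start, dist_break = r$distal$start,
                 status = "unresolved", stringsAsFactors = FALSE)))
    jrows <- jrows[!ids %in% drop_ids]
  }
  list(s = s, jrows = jrows, profile = profile, pieces = pieces,
       reserved = c(reserved, bs), used = used, pattern = pattern,
       h2 = isTRUE(cons$h2), unresolved = unresolved)
}

#' Simulate a multi-segment rearrangement with its junctions
#'
#' Builds a replication plan for the requested pattern (an ordered list
#' of oriented reference pieces forming the derived haplotype), derives
#' the copy-number profile from the plan's per-base coverage, and emits
#' one junction per reference-discontinuous adjacency.  The
#' DUP-TRP-DUP pattern is generated in its inverted-triplication form
#' (DUP-TRP/INV-DUP): the first template switch joins the distal end of
#' the distal duplication to the distal end of the triplication in
#' inverted orientation and the second switch restores the original
#' direction.  Junction signatures are planted on the distal side of
#' each plantable adjacency.
#'
#' @param ref a `ref_store`
#' @param pattern one of `"DUP"`, `"DUP-NML-DUP"`, `"DUP-TRP-DUP"`,
#'   `"DUP-NML-DEL"`, `"DUP-QUAD-TRP"`, `"DUP-NML-DUP-NML-DUP"`
#' @param seed integer seed
#' @param individual_id label
#' @param chrom chromosome to rearrange
#' @param annot optional repeat annotations (enables the LCR-mediated
#'   junction placements)
#' @param constraints list of layout constraints (`prox_range`,
#'   `dist_range`, `dist_in`, `h2`, `lcr_jct`)
#' @param categories join-point categories to plant, in order
#' @param drop_junctions indices of junctions to withhold as unresolved
#' @param params a [signature_params()]
#' @return a list: `ref` (edited), `profile` (a `cnv_profile`),
#'   `junctions` (list of `junction`s), `truth` (data.frame), `pieces`
#'   (the ordered oriented reference pieces of the derived haplotype,
#'   each a list with `start`, `end`, `strand`),
#'   `unresolved` (data.frame or `NULL`)
#' @export
simulate_rearrangement <- function(ref, pattern, seed = NULL,
                                   individual_id = "ind1",
                                   chrom = names(ref$seqs)[1L],
                                   annot = NULL, constraints = list(),
                                   categories = character(0),
                                   drop_junctions = integer(0),
                                   params = signature_params()) {
  if (!pattern %in% rearrangement_patterns)
    stop("unknown pattern '", pattern, "'; supported: ",
         paste(rearrangement_patterns, collapse = ", "))
  with_seed(seed, {
    core <- sim_rearr_core(as.character(ref$seqs[[chrom]]), chrom, pattern,
                           individual_id, annot, constraints, categories,
                           numeric(0), params, drop_junctions)
    ref$seqs[[chrom]] <- Biostrings::DNAString(core$s)
    finish_rearrangement(core, ref, individual_id, params)
  })
}

assemble_reads <- function(jrows, s, chrom) {
  sref <- ref_store(stats::setNames(s, chrom))
  lapply(jrows, function(r) {
    r$read <- paste0(ref_fetch_interval(sref, r$proximal), r$insertion,
                     ref_fetch_interval(sref, r$distal))
    r
  })
}

finish_rearrangement <- function(core, ref, individual_id, params) {
  junctions <- lapply(core$jrows, function(r)
    junction(r$junction_id, individual_id, r$read, r$proximal, r$distal,
             ref = ref, params = params))
  truth <- do.call(rbind, lapply(core$jrows, function(r)
    data.frame(junction_id = r$junction_id, individual_id = individual_id,
               structure_label = core$pattern,
               planted_category = r$planted_category,
               planted_mh_len = r$planted_mh_len,
               planted_mhe_len = r$planted_mhe_len,
               planted_mhe_identity = r$planted_mhe_identity,
               planted_insertion_len = r$planted_insertion_len,
               planted_priming = r$planted_priming,
               templated = r$templated, stringsAsFactors = FALSE)))
  list(ref = ref, profile = core$profile, junctions = junctions,
       truth = truth, pieces = core$pieces, unresolved = core$unresolved)
}

# -------------------------------------------------------------------------
# cohort and fixture generators

# default category mixture of planted join-points, apportioned from the
# observed join-point spectrum (counts over 57 sequenced join-points)
joinpoint_spectrum <- c(one_bp_match = 3, microhomology = 15,
                        microhomeology = 19, alu_alu_chimera = 3,
                        line_line_chimera = 1, blunt = 2, insertion = 13,
                        paralogous_repeat_other = 1)

# default rearrangement-pattern mixture over individuals (single
# duplication 66%, DUP-NML-DUP 18%, DUP-TRP-DUP 6%, other CGR 10% split
# between the three observed other patterns)
pattern_spectrum <- c(DUP = 0.66, `DUP-NML-DUP` = 0.18,
                      `DUP-TRP-DUP` = 0.06, `DUP-NML-DUP-NML-DUP` = 0.04,
                      `DUP-NML-DEL` = 0.04, `DUP-QUAD-TRP` = 0.02)

# LCR cluster layout on the simulated chromosome: six repeat blocks
# distal to the dosage-sensitive locus, with LCRA1a / LCRA1b the
# inverted pair
lcr_cluster_layout <- function(chrom) {
  rbind(repeat_annotation(chrom, 37000, 38200, "LCR", "LCRC", "LCR", "+"),
        repeat_annotation(chrom, 38700, 41200, "LCR", "LCRA1a", "LCR", "+"),
        repeat_annotation(chrom, 41700, 42900, "LCR", "LCR2", "LCR", "+"),
        repeat_annotation(chrom, 43400, 44600, "LCR", "LCR3", "LCR", "+"),
        repeat_annotation(chrom, 45100, 47600, "LCR", "LCRA1b", "LCR", "-"),
        repeat_annotation(chrom, 48100, 49300, "LCR", "LCRD", "LCR", "+"))
}

#' Simulate a miniature rearrangement cohort
#'
#' Generates a complete cohort on one shared simulated chromosome: a
#' reference with a distal low-copy-repeat cluster (LCRC, LCRA1a, LCR2,
#' LCR3, LCRA1b, LCRD; LCRA1b is an inverted, slightly diverged copy of
#' LCRA1a), per-individual rearrangements drawn from the default pattern
#' mixture by largest-remainder apportionment (so the realised pattern
#' frequencies equal the mixture exactly), junctions with planted
#' signatures on each plantable adjacency, and a truth table.  A fixed
#' fraction of individuals (56% by default) has its distal-most
#' breakpoint placed inside the LCR cluster; among DUP-NML-DUP
#' individuals a fixed number (3 of 9 at the default size) has the
#' copy-neutral region inside the LCRA1a..LCRA1b span, emulating
#' possible H2-inversion-haplotype single duplications.
#'
#' @param n_individuals cohort size (default 50)
#' @param seed integer seed
#' @param chrom_length shared chromosome length (default 60 kb)
#' @param p_distal_lcr fraction of individuals whose distal-most
#'   breakpoint is placed in the LCR cluster (default 0.56)
#' @param n_h2 number of DUP-NML-DUP individuals with the copy-neutral
#'   region inside the LCRA1a..LCRA1b span (default: 1/3 of them)
#' @param pattern_weights named weights over the six supported patterns
#' @param category_weights named weights over plantable join-point
#'   categories
#' @param params a [signature_params()]
#' @return a list: `ref`, `profiles`, `junctions`, `truth`,
#'   `annotations`, `pattern_truth`, `region` (the LCR-cluster
#'   interval), `params`
#' @export
simulate_cohort <- function(n_individuals = 50L, seed = 1L,
                            chrom_length = 60000L, p_distal_lcr = 0.56,
                            n_h2 = NULL, pattern_weights = pattern_spectrum,
                            category_weights = NULL,
                            params = signature_params()) {
  chrom <- "chrXs"
  with_seed(seed, {
    s <- paste(rand_bases(chrom_length, 0.41), collapse = "")
    annot <- lcr_cluster_layout(chrom)
    # LCRA1b: inverted, ~99% identical copy of LCRA1a
    a1a_iv <- annot[annot$name == "LCRA1a", ]
    a1b_iv <- annot[annot$name == "LCRA1b", ]
    a1a <- str_chars(substr(s, a1a_iv$start + 1L, a1a_iv$end))
    mut <- stats::runif(length(a1a)) < 0.01
    a1a[mut] <- vapply(a1a[mut], function(x)
      sample(setdiff(DNA_BASES, x), 1L), character(1))
    s <- splice_str(s, a1b_iv$start, revcomp_chr(paste(a1a, collapse = "")))

    pats <- rep(names(pattern_weights),
                apportion(pattern_weights, n_individuals))
    pats <- sample(pats)
    dnld <- which(pats == "DUP-NML-DUP")
    if (is.null(n_h2)) n_h2 <- length(dnld) %/% 3L
    h2_ids <- if (length(dnld)) dnld[seq_len(min(n_h2, length(dnld)))] else
      integer(0)
    forced_in <- sort(unique(c(h2_ids, which(pats == "DUP-TRP-DUP"))))
    n_in <- apportion(c(p_distal_lcr, 1 - p_distal_lcr), n_individuals)[1L]
    pool <- setdiff(seq_len(n_individuals), forced_in)
    extra_in <- if (n_in > length(forced_in))
      sample(pool, n_in - length(forced_in)) else integer(0)
    in_cluster <- sort(c(forced_in, extra_in))

    plantable_per <- c(DUP = 1L, `DUP-NML-DUP` = 2L, `DUP-TRP-DUP` = 1L,
                       `DUP-NML-DEL` = 2L, `DUP-QUAD-TRP` = 1L,
                       `DUP-NML-DUP-NML-DUP` = 3L)
    n_plant <- sum(plantable_per[pats]) - length(h2_ids)  # h2 jct2 is forced
    if (is.null(category_weights))
      category_weights <- joinpoint_spectrum[c("blunt", "one_bp_match",
                                               "microhomology",
                                               "microhomeology", "insertion")]
    cats <- sample(rep(names(category_weights),
                       apportion(category_weights, n_plant)))

    cluster <- gi(chrom, min(annot$start), max(annot$end))
    reserved <- numeric(0)
    profiles <- list(); jrows <- list(); truth <- list(); ptruth <- list()
    ci <- 1L
    # individuals with forced LCR placements (DUP-TRP-DUP junctions in
    # LCRA1a/LCRA1b, H2-style copy-neutral regions) are generated first
    # so the repeat blocks are not crowded out by free-floating
    # in-cluster breakpoints
    prio <- ifelse(pats == "DUP-TRP-DUP", 1L,
                   ifelse(seq_len(n_individuals) %in% h2_ids, 2L, 3L))
    for (i in order(prio, seq_len(n_individuals))) {
      id <- sprintf("SIM%04d", i)
      cons <- list(prox_range = c(3000L, 30000L),
                   dist_range = c(30500L, as.integer(cluster$start - 500L)),
                   dist_in = if (i %in% extra_in) cluster else NULL,
                   mid_max = cluster$start - 500L,
                   h2 = i %in% h2_ids,
                   lcr_jct = pats[i] == "DUP-TRP-DUP")
      avail <- if (ci <= length(cats)) cats[ci:length(cats)] else character(0)
      core <- sim_rearr_core(s, chrom, pats[i], id, annot, cons,
                             avail, reserved, params, build_reads = FALSE)
      s <- core$s
      ci <- ci + core$used
      reserved <- core$reserved
      profiles[[id]] <- core$profile
      jrows <- c(jrows, lapply(core$jrows, function(r) c(r, list(iid = id))))
      ptruth[[id]] <- data.frame(individual_id = id, pattern = pats[i],
                                 in_cluster = i %in% in_cluster,
                                 h2 = i %in% h2_ids, stringsAsFactors = FALSE)
    }
    jrows <- assemble_reads(jrows, s, chrom)
    ref <- ref_store(stats::setNames(s, chrom))
    junctions <- lapply(jrows, function(r)
      junction(r$junction_id, r$iid, r$read, r$proximal, r$distal,
               ref = ref, params = params))
    truth <- do.call(rbind, lapply(jrows, function(r)
      data.frame(junction_id = r$junction_id, individual_id = r$iid,
                 structure_label = NA_character_,
                 planted_category = r$planted_category,
                 planted_mh_len = r$planted_mh_len,
                 planted_mhe_len = r$planted_mhe_len,
                 planted_mhe_identity = r$planted_mhe_identity,
                 planted_insertion_len = r$planted_insertion_len,
                 planted_priming = r$planted_priming,
                 templated = r$templated, stringsAsFactors = FALSE)))
    ptruth <- do.call(rbind, ptruth)
    truth$structure_label <- ptruth$pattern[match(truth$individual_id,
                                                  ptruth$individual_id)]
    list(ref = ref, profiles = profiles, junctions = junctions,
         truth = truth, annotations = annot, pattern_truth = ptruth,
         region = cluster, params = params)
  })
}

#' Simulate a set of isolated junctions spanning all categories
#'
#' Plants `n` junctions, each on its own private chromosome, with the
#' category mixture apportioned from the observed join-point spectrum by
#' default (so realised category fractions are the mixture exactly).
#' Chimeric categories come with matching repeat annotations.
#'
#' @param n number of junctions
#' @param seed integer seed
#' @param category_counts named integer vector of exact per-category
#'   counts (overrides the default apportionment)
#' @param params a [signature_params()]
#' @return a list: `ref`, `junctions`, `truth`, `annotations`
#' @export
simulate_junction_set <- function(n = 1000L, seed = 1L,
                                  category_counts = NULL,
                                  params = signature_params()) {
  if (is.null(category_counts)) {
    category_counts <- stats::setNames(apportion(joinpoint_spectrum, n),
                                       names(joinpoint_spectrum))
  }
  stopifnot(sum(category_counts) == n)
  with_seed(seed, {
    cats <- sample(rep(names(category_counts), category_counts))
    flank <- params$flank_window
    a <- flank + 100L
    b <- a + 2L * flank
    clen <- b + flank + 100L
    seqs <- character(n); names(seqs) <- sprintf("jct%04d", seq_len(n))
    jrows <- list(); annots <- list()
    for (i in seq_len(n)) {
      s <- paste(rand_bases(clen, 0.41), collapse = "")
      spec <- list(category = cats[i])
      res <- plant_on_string(s, names(seqs)[i], a, b, spec, params)
      seqs[i] <- res$s
      jrows[[i]] <- res
      if (!is.null(res$annotations)) annots[[length(annots) + 1L]] <-
        res$annotations
    }
    ref <- ref_store(seqs)
    junctions <- lapply(seq_len(n), function(i)
      junction(names(seqs)[i], sprintf("IND%04d", i), jrows[[i]]$read,
               jrows[[i]]$proximal, jrows[[i]]$distal, ref = ref,
               params = params))
    truth <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(junction_id = names(seqs)[i],
                 individual_id = sprintf("IND%04d", i),
                 structure_label = NA_character_, jrows[[i]]$truth,
                 stringsAsFactors = FALSE)))
    annotations <- if (length(annots)) do.call(rbind, annots) else NULL
    list(ref = ref, junctions = junctions, truth = truth,
         annotations = annotations)
  })
}

#' Write / read a truth table
#' @param truth data.frame as produced by the simulators
#' @param path TSV path
#' @param seed recorded in the header
#' @return `path` (writer) / data.frame (reader)
#' @export
write_truth_table <- function(truth, path, seed = NULL) {
  write_tsv_with_header(truth, path, tsv_header(seed))
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) read_tsv_table(path)

#' Simulate junctions whose flank similarity decays with distance
#'
#' Builds substrate-window pairs that emulate the similarity landscape
#' around microhomeology-mediated join-points: a microhomeology block is
#' planted against the junction and, outside it, the distal window is a
#' copy of the proximal window mutated with a per-base probability that
#' grows linearly with the distance to the block (up to a ceiling of
#' 0.75, the identity floor of unrelated sequence).  The two window
#' orientations of each pair are labelled with the planted priming and
#' target-annealing groups, ready for [aggregate_by_group()].
#'
#' @param n number of junction pairs
#' @param seed integer seed
#' @param slope mutation-probability increase per bp of distance
#' @param mhe_len,mhe_mismatches planted block geometry
#' @param params a [signature_params()]
#' @return a list of `(profile, group, base)` entries
#' @export
simulate_similarity_fixture <- function(n = 40L, seed = 1L, slope = 0.005,
                                        mhe_len = 10L, mhe_mismatches = 2L,
                                        params = signature_params()) {
  with_seed(seed, {
    r <- params$flank_window
    entries <- list()
    for (i in seq_len(n)) {
      P <- rand_bases(2L * r)
      D <- P
      a <- r
      idx <- function(o) a + 1L + o
      # mutation probability by distance to the block edges
      left_o <- seq.int(-r, -mhe_len - 1L)
      right_o <- seq.int(0L, r - 1L)
      for (o in c(left_o, right_o)) {
        d <- if (o < 0L) -o - mhe_len else o + 1L
        if (stats::runif(1) < min(0.75, slope * d))
          D[idx(o)] <- sample(setdiff(DNA_BASES, P[idx(o)]), 1L)
      }
      # the block: exact copy with planted interior mismatches
      mm <- sample(seq.int(-mhe_len + 1L, -2L), mhe_mismatches)
      for (o in mm)
        D[idx(o)] <- sample(setdiff(DNA_BASES, P[idx(o)]), 1L)
      sp <- substrate_pair(paste(P, collapse = ""), paste(D, collapse = ""),
                           a, junction_id = sprintf("dec%03d", i))
      mh <- detect_microhomology(sp)
      mhe <- detect_microhomeology(sp, mh, params)
      aln <- align_substrates(sp, mh, mhe, params)
      prof <- windowed_similarity(aln, params, group = "microhomeology")
      entries[[length(entries) + 1L]] <-
        list(profile = prof, group = "microhomeology_priming",
             base = "proximal")
      entries[[length(entries) + 1L]] <-
        list(profile = prof, group = "microhomeology_target",
             base = "distal")
    }
    entries
  })
}
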