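#' Moving-window similarity profile of an anchored alignment
#'
#' For every alignment column, computes the sequence similarity inside a
#' centred window of `similarity_window` columns (20 by default):
#' matched columns divided by columns where neither sequence has a gap
#' (the `"all"` denominator switch divides by all window columns
#' instead).  Windows at the alignment edges use the available columns;
#' a window containing only gap columns yields `NA`, the gap marker
#' (rendered white in heat maps).  The per-column values are reported in
#' two orientations: proximal-as-base and distal-as-base, where columns
#' at which the base sequence itself has a gap carry the gap marker.
#'
#' @param aln a `pairwise_alignment` (see [align_substrates()])
#' @param params a [signature_params()]
#' @param group optional group label carried into aggregation
#' @return an object of class `"similarity_profile"`: per-column
#'   `values`, orientation-masked `prox_base`/`dist_base` vectors, gap
#'   masks, `anchor_col`, `block_cols`.
#' @export
windowed_similarity <- function(aln, params = signature_params(),
                                group = NA_character_) {
  pc <- str_chars(aln$aligned_proximal)
  dc <- str_chars(aln$aligned_distal)
  n <- length(pc)
  stopifnot(n == length(dc))
  pg <- pc == "-"; dg <- dc == "-"
  pair <- !pg & !dg
  match <- pair & pc == dc & pc != "N"
  half <- params$similarity_window %/% 2L
  cm <- c(0, cumsum(match)); cp <- c(0, cumsum(pair))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (params$similarity_window - half - 1L), n)
  nm <- cm[hi + 1L] - cm[lo]
  np <- cp[hi + 1L] - cp[lo]
  vals <- ifelse(np > 0,
                 if (identical(params$similarity_denominator, "all"))
                   nm / (hi - lo + 1L) else nm / np,
                 NA_real_)
  structure(list(
    junction_id = aln$junction_id,
    group = group,
    values = vals,
    prox_base = ifelse(pg, NA_real_, vals),
    dist_base = ifelse(dg, NA_real_, vals),
    prox_gap = pg, dist_gap = dg,
    anchor_col = aln$anchor_col,
    block_cols = aln$block_cols
  ), class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("Similarity profile %s: %d columns%s, mean %.3f\n",
              x$junction_id, length(x$values),
              if (!is.na(x$group)) paste0(" (", x$group, ")") else "",
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

# project a profile onto one base sequence and return the similarity
# value at each bp distance (1..max_d) from the block edges, averaging
# the two flanks where both exist
profile_distance_series <- function(profile, base = c("proximal", "distal"),
                                    max_d = 150L) {
  base <- match.arg(base)
  gap <- if (base == "proximal") profile$prox_gap else profile$dist_gap
  vals <- profile$values[!gap]           # base coordinates
  # an absent block (blunt join) is an empty block at the junction: the
  # first distance-1 columns are those immediately flanking the anchor
  edges <- if (!is.null(profile$block_cols)) profile$block_cols
           else c(profile$anchor_col + 1L, profile$anchor_col)
  # base positions of the block edges
  left_edge <- sum(!gap[seq_len(edges[1L] - 1L)])          # last base before block
  right_edge <- sum(!gap[seq_len(min(edges[2L], length(gap)))]) + 1L
  out <- rep(NA_real_, max_d)
  for (d in seq_len(max_d)) {
    v <- c(if (left_edge - d + 1L >= 1L) vals[left_edge - d + 1L],
           if (right_edge + d - 1L <= length(vals)) vals[right_edge + d - 1L])
    v <- v[!is.na(v)]
    if (length(v)) out[d] <- mean(v)
  }
  out
}

#' Aggregate similarity profiles by junction group
#'
#' Summarises similarity against distance from the join-point block
#' edges, for the four canonical groups: both sides of blunt junctions,
#' both sides of junctions with a microhomology only, and the priming
#' and target-annealing sides of junctions carrying a microhomeology.
#' For each group and each distance 1..150 bp the mean similarity over
#' contributing junction sides is reported, along with a centred
#' moving-average smoothed series.
#'
#' @param profiles a list; each element a list with `profile` (a
#'   `similarity_profile`), `group` (one of `"blunt"`,
#'   `"microhomology_only"`, `"microhomeology_priming"`,
#'   `"microhomeology_target"`) and `base` (`"proximal"` or
#'   `"distal"`), as produced by [similarity_profiles()].
#' @param params a [signature_params()]
#' @param max_d maximum distance (bp) from the block edge
#' @return a data.frame (`group`, `distance`, `mean`, `n`, `smoothed`)
#'   of class `"aggregate_similarity"`; empty groups are omitted with a
#'   warning.
#' @export
aggregate_by_group <- function(profiles, params = signature_params(),
                               max_d = 150L) {
  groups <- c("blunt", "microhomology_only", "microhomeology_priming",
              "microhomeology_target")
  out <- list()
  for (g in groups) {
    sides <- Filter(function(x) identical(x$group, g), profiles)
    if (!length(sides)) {
      warning("no profiles in group '", g, "'; group omitted")
      next
    }
    series <- vapply(sides, function(x)
      profile_distance_series(x$profile, x$base, max_d), numeric(max_d))
    series <- matrix(series, nrow = max_d)
    mu <- rowMeans(series, na.rm = TRUE)
    nn <- rowSums(!is.na(series))
    mu[nn == 0L] <- NA_real_
    out[[g]] <- data.frame(group = g, distance = seq_len(max_d),
                           mean = mu, n = nn,
                           smoothed = moving_average(mu, params$smooth_width),
                           stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(0), distance = integer(0),
               mean = numeric(0), n = integer(0), smoothed = numeric(0))
  rownames(res) <- NULL
  class(res) <- c("aggregate_similarity", "data.frame")
  res
}

# centred moving average (width odd); NA values are dropped windowwise
moving_average <- function(x, width) {
  half <- width %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Build grouped similarity profiles for a set of classified junctions
#'
#' Combines [align_substrates()] and [windowed_similarity()] for every
#' junction whose category belongs to one of the four aggregate groups,
#' assigning each window orientation to its group: blunt and
#' microhomology-only junctions contribute both orientations; junctions
#' with a microhomeology contribute the priming-substrate orientation to
#' the priming group and the other orientation to the target-annealing
#' group (junctions with an undetermined priming side are skipped).
#'
#' @param junctions list of `junction`s
#' @param calls matching list of `joinpoint_call`s
#' @param ref a `ref_store`
#' @param params a [signature_params()]
#' @return a list of `(profile, group, base)` entries suitable for
#'   [aggregate_by_group()]
#' @export
similarity_profiles <- function(junctions, calls, ref,
                                params = signature_params()) {
  stopifnot(length(junctions) == length(calls))
  out <- list()
  for (k in seq_along(junctions)) {
    cl <- calls[[k]]
    if (cl$withheld) next
    grp <- switch(cl$category,
                  blunt = "blunt",
                  microhomology = "microhomology_only",
                  microhomeology = "microhomeology",
                  NULL)
    if (is.null(grp)) next
    sp <- extract_substrate_pair(junctions[[k]], ref, params)
    aln <- align_substrates(sp, cl$mh, cl$mhe, params)
    prof <- windowed_similarity(aln, params, group = grp)
    if (grp == "microhomeology") {
      side <- cl$mhe$priming_side
      if (is.na(side) || side == "undetermined") next
      prim <- if (side == "proximal") "proximal" else "distal"
      targ <- if (side == "proximal") "distal" else "proximal"
      out[[length(out) + 1L]] <- list(profile = prof,
                                      group = "microhomeology_priming",
                                      base = prim)
      out[[length(out) + 1L]] <- list(profile = prof,
                                      group = "microhomeology_target",
                                      base = targ)
    } else {
      out[[length(out) + 1L]] <- list(profile = prof, group = grp,
                                      base = "proximal")
      out[[length(out) + 1L]] <- list(profile = prof, group = grp,
                                      base = "distal")
    }
  }
  out
}

#' Render a similarity heat map
#'
#' Writes the numeric matrix as TSV (top band proximal-as-base, bottom
#' band distal-as-base) and, optionally, a PNG image with the
#' conventional colour scale: orange for high similarity, blue for low,
#' white for gap columns.
#'
#' @param profile a `similarity_profile`
#' @param out output path stem; `<out>.tsv` is always written,
#'   `<out>.png` when `image = TRUE`
#' @param image write the PNG image
#' @return the TSV path, invisibly
#' @export
render_heatmap <- function(profile, out, image = TRUE) {
  mat <- rbind(proximal_base = profile$prox_base,
               distal_base = profile$dist_base)
  colnames(mat) <- seq_len(ncol(mat))
  tsv <- paste0(out, ".tsv")
  df <- data.frame(band = rownames(mat), mat, check.names = FALSE)
  write_tsv_with_header(df, tsv, tsv_header(extra = sprintf(
    "# junction: %s  anchor_col: %d", profile$junction_id,
    profile$anchor_col)))
  if (image) {
    png_path <- paste0(out, ".png")
    grDevices::png(png_path, width = 900, height = 220)
    on.exit(grDevices::dev.off())
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#E66101"))(101)
    z <- t(mat[2:1, , drop = FALSE])
    graphics::image(x = seq_len(ncol(mat)), y = 1:2, z = z,
                    col = pal, zlim = c(0, 1), axes = FALSE,
                    xlab = "alignment column", ylab = "",
                    main = profile$junction_id, useRaster = FALSE)
    graphics::axis(1)
    graphics::axis(2, at = 1:2, labels = c("distal", "proximal"),
                   las = 1, tick = FALSE)
    graphics::abline(v = profile$anchor_col + 0.5, lty = 2)
  }
  invisible(tsv)
}

#' Read back a heat-map matrix TSV
#' @param path TSV written by [render_heatmap()]
#' @return a 2-row numeric matrix
#' @export
read_heatmap_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- seq_len(ncol(m))
  m
}

#' Plot aggregate similarity-vs-distance curves
#' @param agg an `aggregate_similarity` data.frame
#' @param out PNG path
#' @return `out`, invisibly
#' @export
plot_aggregate_similarity <- function(agg, out) {
  cols <- c(blunt = "#D7191C", microhomology_only = "#1A9641",
            microhomeology_priming = "#2C7BB6",
            microhomeology_target = "#7B3294")
  present <- intersect(names(cols), unique(agg$group))
  grDevices::png(out, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = c(1, max(agg$distance)), ylim = c(0, 1),
       xlab = "distance to the join-point block edge (bp)",
       ylab = "mean similarity (20-bp moving window)")
  for (g in present) {
    d <- agg[agg$group == g, ]
    graphics::points(d$distance, d$mean, col = cols[[g]], pch = 16,
                     cex = 0.4)
    graphics::lines(d$distance, d$smoothed, col = cols[[g]], lwd = 2)
  }
  graphics::legend("topright", legend = present, col = cols[present],
                   lwd = 2, bty = "n")
  invisible(out)
}
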