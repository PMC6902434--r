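copy_states <- c("DEL", "NML", "DUP", "TRP", "QUAD")

#' Copy-number profile of one individual
#'
#' An ordered set of copy-state segments on one chromosome, relative to
#' the single-copy male X baseline (DEL < NML < DUP < TRP < QUAD).
#' Segments must be sorted, non-overlapping and maximally merged
#' (adjacent segments differ in state); adjacent same-state segments are
#' merged automatically.
#'
#' @param individual_id label
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `state`
#' @return an object of class `"cnv_profile"`
#' @export
cnv_profile <- function(individual_id, segments) {
  need <- c("chrom", "start", "end", "state")
  stopifnot(all(need %in% names(segments)))
  segments <- segments[need]
  bad <- setdiff(unique(segments$state), copy_states)
  if (length(bad))
    stop("unknown copy state(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(copy_states, collapse = "<"), ")")
  if (length(unique(segments$chrom)) > 1L)
    stop("a profile must live on a single chromosome")
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1L) {
    if (any(segments$start[-1L] < segments$end[-nrow(segments)]))
      stop("segments overlap")
    # merge adjacent same-state runs
    keep <- c(TRUE, segments$state[-1L] != segments$state[-nrow(segments)] |
                segments$start[-1L] != segments$end[-nrow(segments)])
    grp <- cumsum(keep)
    segments <- do.call(rbind, lapply(split(segments, grp), function(g)
      data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
                 state = g$state[1L], stringsAsFactors = FALSE)))
  }
  rownames(segments) <- NULL
  structure(list(individual_id = as.character(individual_id),
                 segments = segments), class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("CNV profile %s (%s): %s\n", x$individual_id,
              x$segments$chrom[1L],
              paste(x$segments$state, collapse = "-")))
  invisible(x)
}

#' Read per-individual CNV segment tables (BED-like TSV)
#' @param path TSV with columns individual_id, chrom, start, end, state
#' @return a list of `cnv_profile`s, one per individual
#' @export
read_cnv_segments <- function(path) {
  df <- read_tsv_table(path)
  need <- c("individual_id", "chrom", "start", "end", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("segment table missing columns: ",
                         paste(miss, collapse = ", "))
  lapply(split(df, df$individual_id), function(g)
    cnv_profile(g$individual_id[1L], g))
}

#' Write CNV segment tables
#' @param profiles list of `cnv_profile`s
#' @param path output path
#' @param seed recorded in the header
#' @return `path`, invisibly
#' @export
write_cnv_segments <- function(profiles, path, seed = NULL) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(individual_id = p$individual_id, p$segments,
               stringsAsFactors = FALSE)))
  write_tsv_with_header(df, path, tsv_header(seed))
}

#' Classify a copy-number profile into a rearrangement pattern
#'
#' The pattern string is the dash-joined sequence of copy states with
#' flanking normal-copy segments trimmed and internal copy-neutral
#' regions kept as `NML`.  Top-level classes follow the published
#' four-row scheme: `DUP` is a single duplication, `DUP-NML-DUP` and
#' `DUP-TRP-DUP` keep their names, and any other profile with at least
#' one copy-number-altered segment is an "other CGR".
#'
#' @param p a `cnv_profile`
#' @return an object of class `"pattern_call"`: `individual_id`,
#'   `pattern`, `top_class`, `h2_flag` (`"none"` until
#'   [apply_h2_rule()] is used), `n_cnv_segments`.
#' @export
classify_pattern <- function(p) {
  stopifnot(inherits(p, "cnv_profile"))
  st <- p$segments$state
  keep <- seq_along(st)
  while (length(keep) && st[keep[1L]] == "NML") keep <- keep[-1L]
  while (length(keep) && st[keep[length(keep)]] == "NML")
    keep <- keep[-length(keep)]
  if (!length(keep)) {
    return(structure(list(individual_id = p$individual_id, pattern = "",
                          top_class = "no_rearrangement", h2_flag = "none",
                          n_cnv_segments = 0L), class = "pattern_call"))
  }
  pat <- paste(st[keep], collapse = "-")
  top <- if (pat == "DUP") "single_duplication"
    else if (pat == "DUP-NML-DUP") "DUP-NML-DUP"
    else if (pat == "DUP-TRP-DUP") "DUP-TRP-DUP"
    else "other_CGR"
  structure(list(individual_id = p$individual_id, pattern = pat,
                 top_class = top, h2_flag = "none",
                 n_cnv_segments = sum(st[keep] != "NML")),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("%s: %s (%s%s)\n", x$individual_id,
              if (nzchar(x$pattern)) x$pattern else "no rearrangement",
              x$top_class,
              if (x$h2_flag != "none") paste0("; ", x$h2_flag) else ""))
  invisible(x)
}

#' Flag DUP-NML-DUP patterns compatible with the H2 inversion haplotype
#'
#' A DUP-NML-DUP profile whose copy-neutral region lies inside the span
#' from the start of the inverted repeat LCRA1a to the end of LCRA1b can
#' be a single duplication on the H2 inversion haplotype displayed
#' against an H1-configured reference.  The classification itself is not
#' changed; the possibility is recorded as a flag.
#'
#' @param call a `pattern_call`
#' @param p the matching `cnv_profile`
#' @param annot repeat annotations containing named intervals `LCRA1a`
#'   and `LCRA1b`
#' @return the updated `pattern_call`
#' @export
apply_h2_rule <- function(call, p, annot) {
  if (call$pattern != "DUP-NML-DUP") return(call)
  a1a <- annot[annot$name == "LCRA1a", , drop = FALSE]
  a1b <- annot[annot$name == "LCRA1b", , drop = FALSE]
  if (nrow(a1a) == 0L || nrow(a1b) == 0L) {
    warning("LCRA1a/LCRA1b annotation missing; H2 flag not evaluated")
    return(call)
  }
  st <- p$segments$state
  idx <- which(st == "NML")
  inner <- idx[idx > 1L & idx < length(st)]
  if (!length(inner)) return(call)
  cnr <- p$segments[inner[1L], ]
  span_chrom <- a1a$chrom[1L]
  if (cnr$chrom == span_chrom && cnr$start >= min(a1a$start) &&
      cnr$end <= max(a1b$end))
    call$h2_flag <- "possible_H2_single_dup"
  call
}

#' Count individuals with breakpoints inside a region
#'
#' A breakpoint is a boundary (start or end) of a copy-number-altered
#' (non-NML) segment.  Membership is half-open: a boundary exactly at
#' the region start counts as inside, one at the region end does not.
#' When annotations are supplied a per-LCR breakdown is added (number of
#' individuals with at least one breakpoint in each named element).
#'
#' @param cohort list of `cnv_profile`s
#' @param region a `genomic_interval`
#' @param annot optional repeat annotations for the per-element rows
#' @return a [frequency_table()] whose first row is the region count
#'   over the cohort
#' @export
breakpoints_in_region <- function(cohort, region, annot = NULL) {
  bp_of <- function(p) {
    cnv <- p$segments[p$segments$state != "NML", , drop = FALSE]
    if (!nrow(cnv)) return(NULL)
    data.frame(chrom = rep(cnv$chrom, 2L), pos = c(cnv$start, cnv$end))
  }
  inside <- function(bp, chrom, lo, hi)
    !is.null(bp) && any(bp$chrom == chrom & bp$pos >= lo & bp$pos < hi)
  n <- length(cohort)
  bps <- lapply(cohort, bp_of)
  cnt <- sum(vapply(bps, inside, logical(1), region$chrom, region$start,
                    region$end))
  rows <- data.frame(label = sprintf("breakpoint in %s",
                                     format_interval(region)),
                     count = cnt, stringsAsFactors = FALSE)
  if (!is.null(annot) && nrow(annot)) {
    for (nm in unique(annot$name)) {
      el <- annot[annot$name == nm, , drop = FALSE][1L, ]
      rows <- rbind(rows, data.frame(
        label = sprintf("breakpoint in %s", nm),
        count = sum(vapply(bps, inside, logical(1), el$chrom, el$start,
                           el$end)),
        stringsAsFactors = FALSE))
    }
  }
  frequency_table(rows$label, rows$count, denominator = n,
                  partition = FALSE)
}

#' Frequency table with guaranteed arithmetic
#'
#' @param label row labels
#' @param count row counts
#' @param denominator common denominator
#' @param partition when `TRUE` (default) the counts must sum to the
#'   denominator (a partition of the cohort); violation is an error
#' @return a data.frame (`label`, `count`, `denominator`, `percent`) of
#'   class `"frequency_table"`
#' @export
frequency_table <- function(label, count, denominator, partition = TRUE) {
  stopifnot(length(label) == length(count))
  if (partition && sum(count) != denominator)
    stop(sprintf("counts (%d) do not sum to the denominator (%d)",
                 sum(count), denominator))
  if (any(count > denominator))
    stop("a count exceeds the denominator")
  denominator <- as.integer(denominator)
  out <- data.frame(label = as.character(label), count = as.integer(count),
                    denominator = rep(denominator, length(label)),
                    percent = if (denominator > 0)
                      100 * count / denominator
                    else rep(NA_real_, length(label)),
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' @export
print.frequency_table <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-32s %5.1f%% (%d/%d)\n", x$label[i], x$percent[i],
                x$count[i], x$denominator[i]))
  invisible(x)
}

pattern_classes <- c(single_duplication = "Single duplication",
                     `DUP-NML-DUP` = "DUP-NML-DUP",
                     `DUP-TRP-DUP` = "DUP-TRP-DUP",
                     other_CGR = "Other CGR")

#' Cohort summaries of rearrangement patterns and join-point categories
#'
#' Builds the two standard cohort tables: rearrangement-pattern
#' frequencies over individuals, and join-point category frequencies
#' over called (non-withheld) join-points.  Withheld join-points are
#' excluded from the category denominator.  An optional coarser
#' meta-analysis grouping (any pattern containing a triplication) is
#' attached as an attribute.
#'
#' @param calls list of `pattern_call`s (one per individual)
#' @param jps list of `joinpoint_call`s (may be empty)
#' @return a list with `patterns` and `joinpoints`, both
#'   [frequency_table()]s, and `trp_containing` (count of individuals
#'   whose pattern contains TRP or QUAD)
#' @export
summarize_cohort <- function(calls, jps = list()) {
  n <- length(calls)
  top <- vapply(calls, function(x) x$top_class, character(1))
  pat_counts <- vapply(names(pattern_classes),
                       function(k) sum(top == k), integer(1))
  patterns <- if (n > 0)
    frequency_table(unname(pattern_classes), pat_counts, n,
                    partition = all(top %in% names(pattern_classes)))
  else frequency_table(character(0), integer(0), 0L, partition = FALSE)
  called <- Filter(function(x) !x$withheld, jps)
  cat_counts <- vapply(joinpoint_categories, function(k)
    sum(vapply(called, function(x) identical(x$category, k), logical(1))),
    integer(1))
  joinpoints <- frequency_table(unname(category_labels[joinpoint_categories]),
                                unname(cat_counts), length(called))
  list(patterns = patterns, joinpoints = joinpoints,
       trp_containing = sum(grepl("TRP|QUAD", vapply(calls, function(x)
         x$pattern, character(1)))))
}
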