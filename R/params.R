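#' Signature-detection parameters
#'
#' Bundles the tunable thresholds of the join-point signature analysis.
#' Defaults follow the published analysis workflow for copy-number-gain
#' breakpoint junctions: microhomology is a shared 100%-identity run of at
#' least 2 bp at the join-point; microhomeology is an imperfect match of at
#' least 5 alignment columns at >= 70% identity, where every gap run is at
#' most 2 nt and is followed (moving away from the junction) by at least
#' 2 matched columns; reference windows extend 150 bp on each side of a
#' break; moving-window similarity uses 20 columns; insertions of 1-20 bp
#' are "small".
#'
#' @param min_microhomology minimum shared-identity run length (bp) called
#'   as microhomology (default 2).
#' @param min_microhomeology_len minimum microhomeology segment length in
#'   alignment columns (default 5).
#' @param microhomeology_identity_cutoff minimum fraction of matched
#'   columns in a microhomeology segment (default 0.70).
#' @param max_gap_run maximum gap-run length (nt) inside a microhomeology
#'   segment (default 2).
#' @param max_gap_runs maximum number of gap runs per microhomeology
#'   segment (default 1: one gap of at most `max_gap_run` nt, the
#'   stringent reading of the definition; raising it admits several
#'   short gaps, which rapidly admits spurious segments on random
#'   sequence).
#' @param min_post_gap_match matched columns required after a gap run,
#'   moving away from the junction (default 2).
#' @param mhe_min_gain alignment-score points (match = +1) by which a
#'   microhomeology segment must exceed the score of the bare exact
#'   microhomology at the join-point (default 2, i.e. two net extra
#'   matches).  Guards against re-labelling a microhomology as
#'   microhomeology on the strength of a short imperfect fringe, in the
#'   same spirit as the post-gap match requirement; the imperfect block
#'   must contribute annealing evidence beyond the perfect core.
#' @param flank_window reference bases taken on each side of a break when
#'   building substrate windows (default 150, i.e. 300-bp windows).
#' @param similarity_window moving-window width, in alignment columns, for
#'   the similarity profile (default 20).
#' @param small_insertion_max largest insertion (bp) classed as "small"
#'   (default 20).
#' @param mhe_search_radius alignment columns searched on each side of the
#'   join-point for microhomeology segments (default 30).
#' @param identity_denominator `"all_columns"` counts gap columns in the
#'   identity denominator (default); `"nongap"` restricts the denominator
#'   to aligned (non-gap) columns, for sensitivity analysis.
#' @param gap_followed_direction direction in which the matched columns
#'   required after a gap run are counted: `"away"` from the junction
#'   (default) or `"toward"` it.
#' @param similarity_denominator moving-window similarity denominator:
#'   `"nongap"` (default, matches over non-gap columns) or `"all"`.
#' @param nw_match,nw_mismatch Needleman-Wunsch match/mismatch scores
#'   (defaults +1/-1).
#' @param nw_gap_open,nw_gap_ext affine gap penalties (positive numbers;
#'   a gap of length L costs `nw_gap_open + L * nw_gap_ext`; defaults
#'   2 and 0.5).
#' @param smooth_width centred moving-average width for the aggregate
#'   similarity curve (odd integer, default 9).
#' @return an object of class `"signature_params"` (a named list).
#' @examples
#' p <- signature_params()
#' p$microhomeology_identity_cutoff
#' @export
signature_params <- function(min_microhomology = 2L,
                             min_microhomeology_len = 5L,
                             microhomeology_identity_cutoff = 0.70,
                             max_gap_run = 2L,
                             max_gap_runs = 1L,
                             min_post_gap_match = 2L,
                             mhe_min_gain = 2L,
                             flank_window = 150L,
                             similarity_window = 20L,
                             small_insertion_max = 20L,
                             mhe_search_radius = 30L,
                             identity_denominator = c("all_columns", "nongap"),
                             gap_followed_direction = c("away", "toward"),
                             similarity_denominator = c("nongap", "all"),
                             nw_match = 1,
                             nw_mismatch = -1,
                             nw_gap_open = 2,
                             nw_gap_ext = 0.5,
                             smooth_width = 9L) {
  identity_denominator <- match.arg(identity_denominator)
  gap_followed_direction <- match.arg(gap_followed_direction)
  similarity_denominator <- match.arg(similarity_denominator)
  num <- c(min_microhomology = min_microhomology,
           min_microhomeology_len = min_microhomeology_len,
           microhomeology_identity_cutoff = microhomeology_identity_cutoff,
           max_gap_run = max_gap_run,
           max_gap_runs = max_gap_runs,
           min_post_gap_match = min_post_gap_match,
           mhe_min_gain = mhe_min_gain,
           flank_window = flank_window,
           similarity_window = similarity_window,
           small_insertion_max = small_insertion_max,
           mhe_search_radius = mhe_search_radius,
           smooth_width = smooth_width)
  if (any(num <= 0)) stop("all signature parameters must be positive")
  if (microhomeology_identity_cutoff > 1)
    stop("microhomeology_identity_cutoff must be in (0, 1]")
  structure(list(
    min_microhomology = as.integer(min_microhomology),
    min_microhomeology_len = as.integer(min_microhomeology_len),
    microhomeology_identity_cutoff = microhomeology_identity_cutoff,
    max_gap_run = as.integer(max_gap_run),
    max_gap_runs = as.integer(max_gap_runs),
    min_post_gap_match = as.integer(min_post_gap_match),
    mhe_min_gain = as.integer(mhe_min_gain),
    flank_window = as.integer(flank_window),
    similarity_window = as.integer(similarity_window),
    small_insertion_max = as.integer(small_insertion_max),
    mhe_search_radius = as.integer(mhe_search_radius),
    identity_denominator = identity_denominator,
    gap_followed_direction = gap_followed_direction,
    similarity_denominator = similarity_denominator,
    nw_match = nw_match,
    nw_mismatch = nw_mismatch,
    nw_gap_open = nw_gap_open,
    nw_gap_ext = nw_gap_ext,
    smooth_width = as.integer(smooth_width)
  ), class = "signature_params")
}

params_fingerprint <- function(params) {
  stopifnot(inherits(params, "signature_params"))
  paste(vapply(names(params), function(n) {
    paste0(n, "=", format(params[[n]]))
  }, character(1)), collapse = " ")
}

#' @export
print.signature_params <- function(x, ...) {
  cat("Join-point signature parameters:\n")
  for (n in names(x)) cat(sprintf("  %-32s %s\n", n, format(x[[n]])))
  invisible(x)
}
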