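joinpoint_categories <- c("blunt", "one_bp_match", "microhomology",
                          "microhomeology", "insertion", "alu_alu_chimera",
                          "line_line_chimera", "paralogous_repeat_other")

# published table row label for each category
category_labels <- c(
  blunt = "Blunt",
  one_bp_match = "Join-points with 1 bp match",
  microhomology = "Microhomology > 2 bp",
  microhomeology = "Microhomeology",
  insertion = "Insertion",
  alu_alu_chimera = "Alu-Alu",
  line_line_chimera = "LINE-LINE",
  paralogous_repeat_other = "Others"
)

#' Classify a join-point into its mutually exclusive category
#'
#' Runs all detectors and applies the category precedence used in
#' join-point tabulations: repeat-chimera classes, then insertion (any
#' read span supported by neither substrate), then microhomeology, then
#' microhomology (at least 2 bp), then a single-bp match, then blunt.
#' Microhomeology takes precedence over microhomology (a join-point
#' showing both is counted as microhomeology), and micro-signatures are
#' not counted for chimeric junctions.  The call retains every raw
#' measurement regardless of the category.
#'
#' @param j a parsed `junction`
#' @param sp its `substrate_pair` (computed from `j` when `NULL`)
#' @param annot repeat annotation data.frame or `NULL`
#' @param params a [signature_params()]
#' @param ref a `ref_store`, needed when `sp` is `NULL`
#' @return an object of class `"joinpoint_call"`.
#' @export
classify_joinpoint <- function(j, sp = NULL, annot = NULL,
                               params = signature_params(), ref = NULL) {
  if (is.null(sp)) {
    if (is.null(ref)) stop("either sp or ref must be supplied")
    sp <- extract_substrate_pair(j, ref, params)
  }
  out <- structure(list(
    junction_id = j$junction_id, individual_id = j$individual_id,
    category = NA_character_, label = NA_character_,
    mh = NULL, mhe = NULL, chimera = NULL,
    insertion_len = NA_integer_, insertion_class = "none",
    withheld = FALSE, reason = NA_character_, flags = j$flags
  ), class = "joinpoint_call")
  if (is.na(j$anchor)) {
    out$withheld <- TRUE
    out$reason <- "unparsed junction (no anchor)"
    return(out)
  }
  mh <- detect_microhomology(sp)
  mhe <- detect_microhomeology(sp, mh, params)
  chim <- call_chimeric_repeat(j, annot)
  ins_len <- nchar(j$insertion)
  out$mh <- mh; out$mhe <- mhe; out$chimera <- chim
  out$insertion_len <- as.integer(ins_len)
  out$insertion_class <- if (ins_len == 0L) "none"
    else if (ins_len <= params$small_insertion_max) "small" else "large"
  out$category <- if (chim$call == "alu_alu") "alu_alu_chimera"
    else if (chim$call == "line_line") "line_line_chimera"
    else if (chim$call == "paralogous_other") "paralogous_repeat_other"
    else if (ins_len >= 1L) "insertion"
    else if (mhe$present) "microhomeology"
    else if (mh$length >= params$min_microhomology) "microhomology"
    else if (mh$length == 1L) "one_bp_match"
    else "blunt"
  out$label <- unname(category_labels[out$category])
  out
}

#' @export
print.joinpoint_call <- function(x, ...) {
  if (x$withheld) {
    cat(sprintf("Join-point %s: withheld (%s)\n", x$junction_id, x$reason))
    return(invisible(x))
  }
  cat(sprintf("Join-point %s: %s", x$junction_id, x$category))
  if (x$category == "microhomology")
    cat(sprintf(" (%d bp '%s')", x$mh$length, x$mh$sequence))
  if (x$category == "microhomeology")
    cat(sprintf(" (%d columns, identity %.2f, priming %s)",
                x$mhe$length, x$mhe$identity, x$mhe$priming_side))
  if (x$category == "insertion")
    cat(sprintf(" (%d bp, %s)", x$insertion_len, x$insertion_class))
  cat("\n")
  invisible(x)
}

#' Flatten join-point calls to a data.frame
#' @param calls list of `joinpoint_call` objects
#' @return a data.frame with one row per call and every measurement
#' @export
joinpoint_call_table <- function(calls) {
  if (!length(calls)) {
    cols <- c("junction_id", "individual_id", "category", "label", "mh_len",
              "mh_seq", "mhe_present", "mhe_len", "mhe_identity",
              "mhe_priming", "mhe_mh_position", "insertion_len",
              "insertion_class", "chimera", "chimera_orientation",
              "withheld", "reason")
    return(as.data.frame(stats::setNames(rep(list(character(0)),
                                             length(cols)), cols)))
  }
  do.call(rbind, lapply(calls, function(x) {
    data.frame(
      junction_id = x$junction_id, individual_id = x$individual_id,
      category = x$category, label = x$label,
      mh_len = if (is.null(x$mh)) NA_integer_ else x$mh$length,
      mh_seq = if (is.null(x$mh)) NA_character_ else x$mh$sequence,
      mhe_present = if (is.null(x$mhe)) NA else x$mhe$present,
      mhe_len = if (is.null(x$mhe)) NA_integer_ else x$mhe$length,
      mhe_identity = if (is.null(x$mhe)) NA_real_ else x$mhe$identity,
      mhe_priming = if (is.null(x$mhe)) NA_character_ else x$mhe$priming_side,
      mhe_mh_position = if (is.null(x$mhe)) NA_character_ else x$mhe$mh_position,
      insertion_len = x$insertion_len,
      insertion_class = x$insertion_class,
      chimera = if (is.null(x$chimera)) NA_character_ else x$chimera$call,
      chimera_orientation = if (is.null(x$chimera)) NA_character_
                            else x$chimera$orientation,
      withheld = x$withheld,
      reason = x$reason,
      stringsAsFactors = FALSE)
  }))
}

#' Write join-point calls as TSV
#' @param calls list of `joinpoint_call`s
#' @param path output path
#' @param seed,params recorded in the header
#' @return `path`, invisibly
#' @export
write_joinpoint_calls <- function(calls, path, seed = NULL, params = NULL) {
  write_tsv_with_header(joinpoint_call_table(calls), path,
                        tsv_header(seed, params))
}
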