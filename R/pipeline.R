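#' Pipeline commands
#'
#' Thin orchestration layer over the package functions, mirroring the
#' command-line interface: `cmd_simulate` writes a complete synthetic
#' cohort fixture, `cmd_call_signatures` runs
#' extract -> detect -> classify -> profile -> aggregate over a junction
#' table, `cmd_summarize` builds the cohort frequency tables, and
#' `cmd_all` chains the three.  All outputs are plain TSV (plus optional
#' PNG figures) with `#` headers carrying the package version, the seed
#' and the parameter fingerprint, so reruns with an identical
#' configuration are byte-identical.
#'
#' @param outdir output directory
#' @param n_individuals cohort size for the simulated fixture
#' @param seed integer seed used for every source of randomness
#' @param params a [signature_params()]
#' @param force overwrite a non-empty output directory
#' @return `cmd_simulate` returns the fixture file paths; the others
#'   return the main result objects, invisibly
#' @name pipeline
NULL

fixture_paths <- function(outdir) {
  list(reference = file.path(outdir, "reference.fa"),
       junctions = file.path(outdir, "junctions.tsv"),
       segments = file.path(outdir, "segments.tsv"),
       annotations = file.path(outdir, "annotations.tsv"),
       truth = file.path(outdir, "truth.tsv"),
       pattern_truth = file.path(outdir, "pattern_truth.tsv"))
}

prepare_outdir <- function(outdir, force) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    stop("output directory ", outdir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outdir
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(outdir, n_individuals = 50L, seed = 1L,
                         params = signature_params(), force = FALSE) {
  prepare_outdir(outdir, force)
  sim <- simulate_cohort(n_individuals = n_individuals, seed = seed,
                         params = params)
  p <- fixture_paths(outdir)
  write_reference_fasta(sim$ref, p$reference)
  write_junction_table(sim$junctions, p$junctions, seed, params)
  write_cnv_segments(sim$profiles, p$segments, seed)
  write_repeat_annotations(sim$annotations, p$annotations, seed)
  write_truth_table(sim$truth, p$truth, seed)
  write_tsv_with_header(sim$pattern_truth, p$pattern_truth,
                        tsv_header(seed))
  message(sprintf("simulated cohort: %d individuals, %d junctions -> %s",
                  n_individuals, length(sim$junctions), outdir))
  invisible(p)
}

#' @rdname pipeline
#' @param reference,junctions,annotations,segments input file paths (for
#'   `cmd_call_signatures` / `cmd_summarize`); defaults are the fixture
#'   names inside `outdir`
#' @param heatmaps also render per-junction similarity heat maps
#' @export
cmd_call_signatures <- function(outdir,
                                reference = fixture_paths(outdir)$reference,
                                junctions = fixture_paths(outdir)$junctions,
                                annotations = fixture_paths(outdir)$annotations,
                                seed = 1L, params = signature_params(),
                                heatmaps = FALSE) {
  ref <- read_reference_fasta(reference)
  jx <- read_junction_table(junctions, ref, params)
  annot <- if (!is.null(annotations) && file.exists(annotations))
    read_repeat_annotations(annotations) else NULL
  if (!length(jx)) {
    warning("empty junction table; writing empty outputs")
    write_joinpoint_calls(list(), file.path(outdir, "joinpoint_calls.tsv"),
                          seed, params)
    return(invisible(list(calls = list(), aggregate = NULL)))
  }
  calls <- lapply(jx, function(j) {
    cl <- classify_joinpoint(j, annot = annot, params = params, ref = ref)
    message(sprintf("junction %s: %s", j$junction_id,
                    if (cl$withheld) paste("withheld -", cl$reason)
                    else cl$category))
    cl
  })
  write_joinpoint_calls(calls, file.path(outdir, "joinpoint_calls.tsv"),
                        seed, params)
  profs <- similarity_profiles(jx, calls, ref, params)
  agg <- withCallingHandlers(
    aggregate_by_group(profs, params),
    warning = function(w) {
      message("aggregate: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_tsv_with_header(agg, file.path(outdir, "aggregate_similarity.tsv"),
                        tsv_header(seed, params))
  if (heatmaps) {
    hdir <- file.path(outdir, "heatmaps")
    dir.create(hdir, showWarnings = FALSE)
    for (e in profs)
      if (e$base == "proximal" || e$group %in% c("blunt",
                                                 "microhomology_only"))
        render_heatmap(e$profile, file.path(hdir, e$profile$junction_id))
  }
  invisible(list(calls = calls, aggregate = agg, profiles = profs))
}

# rebuild lightweight call objects from a written call table
calls_from_table <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(junction_id = df$junction_id[i],
                   individual_id = df$individual_id[i],
                   category = df$category[i], label = df$label[i],
                   withheld = isTRUE(df$withheld[i]),
                   reason = df$reason[i]), class = "joinpoint_call")
  })
}

#' @rdname pipeline
#' @param calls path to a join-point call table written by
#'   `cmd_call_signatures`
#' @param region a `genomic_interval` for the breakpoint-grouping table;
#'   by default the span of the annotated LCR cluster
#' @export
cmd_summarize <- function(outdir,
                          segments = fixture_paths(outdir)$segments,
                          annotations = fixture_paths(outdir)$annotations,
                          calls = file.path(outdir, "joinpoint_calls.tsv"),
                          region = NULL, seed = 1L,
                          params = signature_params()) {
  if (!file.exists(segments))
    stop("segment table ", segments, " not found; run the simulate or ",
         "import step first")
  profiles <- read_cnv_segments(segments)
  annot <- if (!is.null(annotations) && file.exists(annotations))
    read_repeat_annotations(annotations) else NULL
  pcalls <- lapply(profiles, function(p) {
    cl <- classify_pattern(p)
    if (!is.null(annot)) cl <- apply_h2_rule(cl, p, annot)
    cl
  })
  if (is.null(region) && !is.null(annot)) {
    lcr <- annot[annot$klass == "LCR", , drop = FALSE]
    if (nrow(lcr))
      region <- gi(lcr$chrom[1L], min(lcr$start), max(lcr$end))
  }
  jcalls <- if (file.exists(calls)) calls_from_table(read_tsv_table(calls))
            else list()
  summ <- summarize_cohort(pcalls, jcalls)
  write_tsv_with_header(summ$patterns,
                        file.path(outdir, "pattern_frequencies.tsv"),
                        tsv_header(seed, params))
  write_tsv_with_header(summ$joinpoints,
                        file.path(outdir, "joinpoint_frequencies.tsv"),
                        tsv_header(seed, params))
  if (!is.null(region)) {
    bir <- breakpoints_in_region(profiles, region, annot)
    write_tsv_with_header(bir, file.path(outdir, "region_breakpoints.tsv"),
                          tsv_header(seed, params))
    summ$region <- bir
  }
  agg_path <- file.path(outdir, "aggregate_similarity.tsv")
  if (file.exists(agg_path)) {
    agg <- read_tsv_table(agg_path)
    class(agg) <- c("aggregate_similarity", "data.frame")
    try(plot_aggregate_similarity(agg,
                                  file.path(outdir, "aggregate_similarity.png")),
        silent = TRUE)
  }
  summ$pattern_calls <- pcalls
  invisible(summ)
}

#' @rdname pipeline
#' @export
cmd_all <- function(outdir, n_individuals = 50L, seed = 1L,
                    params = signature_params(), force = FALSE,
                    heatmaps = FALSE) {
  cmd_simulate(outdir, n_individuals, seed, params, force)
  cmd_call_signatures(outdir, seed = seed, params = params,
                      heatmaps = heatmaps)
  cmd_summarize(outdir, seed = seed, params = params)
}
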