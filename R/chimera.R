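repeat_klasses <- c("LCR", "Alu", "LINE", "self_chain", "SegDup")

#' Repeat annotation record
#' @param chrom,start,end interval (printed-coordinate convention)
#' @param klass one of `"LCR"`, `"Alu"`, `"LINE"`, `"self_chain"`,
#'   `"SegDup"`
#' @param name element name (e.g. `"LCRA1a"`, `"AluSx1"`, `"L1PA5"`)
#' @param family element family label
#' @param orientation `"+"` or `"-"`
#' @return a one-row data.frame
#' @export
repeat_annotation <- function(chrom, start, end, klass, name,
                              family = name, orientation = "+") {
  if (!klass %in% repeat_klasses)
    stop("klass must be one of: ", paste(repeat_klasses, collapse = ", "))
  if (!nzchar(name)) stop("repeat name must be non-empty")
  data.frame(chrom = chrom, start = as.double(start), end = as.double(end),
             klass = klass, name = name, family = family,
             orientation = orientation, stringsAsFactors = FALSE)
}

#' Read a repeat annotation table (BED-like TSV with a klass column)
#' @param path TSV with columns chrom, start, end, klass, name, family,
#'   orientation
#' @return a data.frame
#' @export
read_repeat_annotations <- function(path) {
  df <- read_tsv_table(path)
  need <- c("chrom", "start", "end", "klass", "name", "family", "orientation")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$klass), repeat_klasses)
  if (length(bad)) stop("unknown repeat klass: ", paste(bad, collapse = ", "))
  df
}

#' Write a repeat annotation table
#' @param annot data.frame of annotations
#' @param path output path
#' @param seed optional seed recorded in the header
#' @return `path`, invisibly
#' @export
write_repeat_annotations <- function(annot, path, seed = NULL) {
  write_tsv_with_header(annot, path, tsv_header(seed))
}

# annotations overlapping a point (half-open intervals)
annot_at <- function(annot, chrom, pos) {
  annot[annot$chrom == chrom & annot$start <= pos & pos < annot$end, ,
        drop = FALSE]
}

#' Call a repeat-mediated chimeric junction
#'
#' A junction is Alu-Alu or LINE-LINE chimeric when both substrate
#' breakpoints fall inside annotated elements of the same class (families
#' may differ, e.g. a chimera between L1PA5 and L1PA3); it is a
#' paralogous-repeat junction when both breakpoints fall in an LCR,
#' segmental-duplication or self-chain block (NAHR-like events between
#' directly oriented paralogous sequences).  The relative orientation of
#' the two elements (direct vs inverted, after accounting for the
#' substrate strands) is recorded.
#'
#' @param j a `junction`
#' @param annot a repeat annotation data.frame, or `NULL`
#' @return a list with `call` (one of `"none"`, `"alu_alu"`,
#'   `"line_line"`, `"paralogous_other"`), `orientation` (`"direct"`,
#'   `"inverted"` or `NA`), the two element names, and a
#'   `no_annotation` flag.
#' @export
call_chimeric_repeat <- function(j, annot = NULL) {
  none <- list(call = "none", orientation = NA_character_,
               proximal_element = NA_character_,
               distal_element = NA_character_, no_annotation = FALSE)
  if (is.null(annot) || nrow(annot) == 0L) {
    none$no_annotation <- TRUE
    return(none)
  }
  pb <- proximal_break(j); db <- distal_break(j)
  # a breakpoint at the very end of a contig window: probe the base on the
  # 5' side of the break so a break at an element's exclusive end still
  # counts as inside it
  pa <- annot_at(annot, j$proximal$chrom,
                 if (j$proximal$strand == "+") pb - 1 else pb)
  da <- annot_at(annot, j$distal$chrom,
                 if (j$distal$strand == "+") db else db - 1)
  if (nrow(pa) == 0L || nrow(da) == 0L) return(none)
  para <- c("LCR", "self_chain", "SegDup")
  pick <- function(x, kl) {
    hit <- x[x$klass %in% kl, , drop = FALSE]
    if (nrow(hit)) hit[1L, , drop = FALSE] else NULL
  }
  for (cls in list(list(k = "Alu", lab = "alu_alu"),
                   list(k = "LINE", lab = "line_line"),
                   list(k = para, lab = "paralogous_other"))) {
    pe <- pick(pa, cls$k); de <- pick(da, cls$k)
    if (!is.null(pe) && !is.null(de)) {
      # element orientation in read coordinates
      po <- if (pe$orientation == j$proximal$strand) "+" else "-"
      dor <- if (de$orientation == j$distal$strand) "+" else "-"
      return(list(call = cls$lab,
                  orientation = if (po == dor) "direct" else "inverted",
                  proximal_element = pe$name, distal_element = de$name,
                  no_annotation = FALSE))
    }
  }
  none
}
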