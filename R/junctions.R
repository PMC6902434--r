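#' Build a breakpoint junction from a read and its two substrate mappings
#'
#' A junction is the sequenced product spanning the fusion of two genomic
#' segments that are discontinuous in the reference.  The proximal
#' interval is the substrate supporting the 5' part of the read, the
#' distal interval the substrate supporting the 3' part; either may be on
#' the minus strand (inverted join).  The read is parsed against the
#' reference: the maximal exact prefix supported by the proximal
#' substrate and the maximal exact suffix supported by the distal
#' substrate determine the anchor (index where the proximal-supported
#' prefix ends), the overlap (microhomology at read level, when prefix
#' and suffix overlap), and the insertion (read span supported by neither
#' substrate).  When several prefix/suffix splits are possible the anchor
#' is the maximal proximal prefix; the overlap length is recorded so
#' downstream calls are split-invariant.
#'
#' @param junction_id,individual_id labels.
#' @param read the junction read (nucleotide string).
#' @param proximal,distal `genomic_interval`s; the proximal break is the
#'   oriented 3' end of `proximal`, the distal break the oriented 5'
#'   start of `distal`.
#' @param ref a `ref_store` used to parse the read; `NULL` skips parsing.
#' @param params a [signature_params()].
#' @return an object of class `"junction"` with fields `anchor`,
#'   `prefix_len`, `suffix_len`, `overlap`, `insertion` and `flags`.
#' @export
junction <- function(junction_id, individual_id, read, proximal, distal,
                     ref = NULL, params = signature_params()) {
  stopifnot(inherits(proximal, "genomic_interval"),
            inherits(distal, "genomic_interval"))
  j <- structure(list(
    junction_id = as.character(junction_id),
    individual_id = as.character(individual_id),
    read = toupper(read),
    proximal = proximal, distal = distal,
    anchor = NA_integer_, prefix_len = NA_integer_, suffix_len = NA_integer_,
    overlap = NA_integer_, insertion = NA_character_,
    flags = character(0)
  ), class = "junction")
  if (nchar(j$read) < 2 * params$flank_window)
    j$flags <- c(j$flags, "short_read")
  if (!is.null(ref)) j <- parse_junction(j, ref)
  j
}

# oriented break coordinates: the proximal break is the 3' end of the
# proximal substrate in read orientation; the distal break is the 5'
# start of the distal substrate in read orientation
proximal_break <- function(j) {
  if (j$proximal$strand == "+") j$proximal$end else j$proximal$start
}
distal_break <- function(j) {
  if (j$distal$strand == "+") j$distal$start else j$distal$end
}

# oriented reference slice of length n starting at the 5' side of the
# proximal substrate continuation toward/past the proximal break;
# anchored so its first base lines up with read base 1
oriented_from_start <- function(ref, chrom, pos5, n, strand) {
  L <- ref_lengths(ref)[[chrom]]
  if (strand == "+") {
    end <- min(pos5 + n, L)
    if (end <= pos5) return("")
    ref_fetch(ref, chrom, pos5, end, "+")
  } else {
    start <- max(pos5 - n, 0)
    if (start >= pos5) return("")
    ref_fetch(ref, chrom, start, pos5, "-")
  }
}

parse_junction <- function(j, ref) {
  n <- nchar(j$read)
  read_c <- str_chars(j$read)
  # proximal: read prefix vs reference continuation from the substrate's
  # oriented 5' start
  p5 <- if (j$proximal$strand == "+") j$proximal$start else j$proximal$end
  pseq <- tryCatch(
    oriented_from_start(ref, j$proximal$chrom, p5, n, j$proximal$strand),
    error = function(e) stop("junction ", j$junction_id, ": ",
                             conditionMessage(e)))
  p <- lcp_len(read_c, str_chars(pseq))
  # distal: read suffix vs reference ending at the substrate's oriented
  # 3' end
  d3 <- if (j$distal$strand == "+") j$distal$end else j$distal$start
  dseq <- if (j$distal$strand == "+") {
    start <- max(d3 - n, 0)
    if (start < d3) ref_fetch(ref, j$distal$chrom, start, d3, "+") else ""
  } else {
    L <- ref_lengths(ref)[[j$distal$chrom]]
    end <- min(d3 + n, L)
    if (end > d3) ref_fetch(ref, j$distal$chrom, d3, end, "-") else ""
  }
  s <- lcp_len(rev(read_c), rev(str_chars(dseq)))
  j$prefix_len <- as.integer(p)
  j$suffix_len <- as.integer(s)
  j$anchor <- as.integer(p)
  if (p + s >= n) {
    j$overlap <- as.integer(p + s - n)
    j$insertion <- ""
  } else {
    j$overlap <- 0L
    j$insertion <- substr(j$read, p + 1L, n - s)
  }
  if (p == 0L || s == 0L) j$flags <- c(j$flags, "unmapped_end")
  j
}

#' @export
print.junction <- function(x, ...) {
  cat(sprintf("Junction %s (%s): read %d bp\n", x$junction_id,
              x$individual_id, nchar(x$read)))
  cat("  proximal:", format_interval(x$proximal), x$proximal$strand, "\n")
  cat("  distal:  ", format_interval(x$distal), x$distal$strand, "\n")
  if (!is.na(x$anchor))
    cat(sprintf("  anchor %d, overlap %d, insertion %d bp\n", x$anchor,
                x$overlap, nchar(x$insertion)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

junction_columns <- c("junction_id", "individual_id", "read",
                      "prox_chrom", "prox_start", "prox_end", "prox_strand",
                      "dist_chrom", "dist_start", "dist_end", "dist_strand")

#' Read a junction table (TSV)
#'
#' Expected columns: `junction_id`, `individual_id`, `read`,
#' `prox_chrom`, `prox_start`, `prox_end`, `prox_strand`, `dist_chrom`,
#' `dist_start`, `dist_end`, `dist_strand`.  Coordinates are the printed
#' convention (length = end - start).  Rows that fail to parse against
#' the reference are flagged, never silently dropped; malformed
#' coordinates raise an error naming the row, and a chromosome absent
#' from the reference raises an error naming the chromosome.
#'
#' @param path TSV path (lines starting with `#` are ignored).
#' @param ref a `ref_store`.
#' @param params a [signature_params()].
#' @return a list of `junction` objects.
#' @export
read_junction_table <- function(path, ref, params = signature_params()) {
  df <- read_tsv_table(path, colClasses = "character")
  missing_cols <- setdiff(junction_columns, names(df))
  if (length(missing_cols))
    stop("junction table missing columns: ",
         paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    coords <- suppressWarnings(as.double(c(row$prox_start, row$prox_end,
                                           row$dist_start, row$dist_end)))
    if (anyNA(coords))
      stop(sprintf("row %d: malformed coordinates", i))
    for (chr in c(row$prox_chrom, row$dist_chrom))
      if (!chr %in% names(ref$seqs))
        stop(sprintf("row %d: chromosome '%s' absent from reference", i, chr))
    junction(row$junction_id, row$individual_id, row$read,
             gi(row$prox_chrom, coords[1], coords[2], row$prox_strand),
             gi(row$dist_chrom, coords[3], coords[4], row$dist_strand),
             ref = ref, params = params)
  })
}

#' Write a junction table (TSV)
#' @param junctions list of `junction` objects
#' @param path output path
#' @param seed optional seed recorded in the header
#' @param params optional [signature_params()] recorded in the header
#' @return `path`, invisibly
#' @export
write_junction_table <- function(junctions, path, seed = NULL,
                                 params = NULL) {
  df <- do.call(rbind, lapply(junctions, function(j) {
    data.frame(junction_id = j$junction_id, individual_id = j$individual_id,
               read = j$read,
               prox_chrom = j$proximal$chrom, prox_start = j$proximal$start,
               prox_end = j$proximal$end, prox_strand = j$proximal$strand,
               dist_chrom = j$distal$chrom, dist_start = j$distal$start,
               dist_end = j$distal$end, dist_strand = j$distal$strand,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(junction_columns)),
                    junction_columns))
  write_tsv_with_header(df, path, tsv_header(seed, params))
}
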