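#' Genomic interval
#'
#' A minimal coordinate container.  Coordinates are held 0-based half-open
#' internally; printed coordinate pairs "start-end" are parsed and emitted
#' unchanged, so an interval printed as `102,778,586-102,779,195` has
#' length `end - start = 609`, matching the arithmetic used for the
#' bracketed lengths in published breakpoint tables.
#'
#' @param chrom chromosome / contig name (non-empty string).
#' @param start,end interval bounds, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `"genomic_interval"`.
#' @examples
#' gi("chrX", 102778586, 102779195)
#' @export
gi <- function(chrom, start, end, strand = "+") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.double(start); end <- as.double(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop(sprintf("invalid interval: start (%s) must be < end (%s)",
                 format(start), format(end)))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format_interval(x), if (x$strand == "-") "(-)" else "(+)", "\n")
  invisible(x)
}

#' Format an interval the way breakpoint tables print coordinates
#' @param x a `genomic_interval`
#' @param commas insert thousands separators
#' @return a string `"chrom: start-end"`
#' @export
format_interval <- function(x, commas = TRUE) {
  fmt <- function(v) if (commas) formatC(v, format = "d", big.mark = ",") else
    formatC(v, format = "d")
  sprintf("%s: %s-%s", x$chrom, fmt(x$start), fmt(x$end))
}

#' Parse a printed coordinate string into an interval
#' @param s a string like `"ChrX: 99,762,680-104,246,638"`
#' @param strand strand to attach
#' @return a `genomic_interval`
#' @export
parse_interval <- function(s, strand = "+") {
  m <- regmatches(s, regexec("^\\s*([^:]+):\\s*([0-9,]+)\\s*-\\s*([0-9,]+)\\s*$", s))[[1L]]
  if (length(m) != 4L) stop("cannot parse coordinate string: ", s)
  num <- function(v) as.double(gsub(",", "", v, fixed = TRUE))
  gi(trimws(m[2L]), num(m[3L]), num(m[4L]), strand)
}

#' Interval length
#' @param x a `genomic_interval`
#' @return `end - start` in bp
#' @export
gi_length <- function(x) x$end - x$start

#' Reference sequence store
#'
#' Wraps a [Biostrings::DNAStringSet] and provides oriented interval
#' lookup: a minus-strand fetch returns the reverse complement.
#'
#' @param sequences a named character vector or `DNAStringSet`.
#' @return an object of class `"ref_store"`.
#' @export
ref_store <- function(sequences) {
  if (is.character(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named")
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  stopifnot(methods::is(sequences, "DNAStringSet"))
  structure(list(seqs = sequences), class = "ref_store")
}

#' @export
print.ref_store <- function(x, ...) {
  cat(sprintf("Reference store: %d sequence(s), %s bp total\n",
              length(x$seqs),
              formatC(sum(as.double(Biostrings::width(x$seqs))),
                      format = "d", big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a reference store
#' @param ref a `ref_store`
#' @return named numeric vector of sequence lengths
#' @export
ref_lengths <- function(ref) {
  stats::setNames(as.double(Biostrings::width(ref$seqs)), names(ref$seqs))
}

#' Fetch an oriented sequence slice
#'
#' @param ref a `ref_store`
#' @param chrom sequence name
#' @param start,end 0-based half-open bounds within the sequence
#' @param strand `"+"` returns the forward slice, `"-"` its reverse
#'   complement
#' @return a character string of length `end - start`
#' @export
ref_fetch <- function(ref, chrom, start, end, strand = "+") {
  stopifnot(inherits(ref, "ref_store"))
  if (!chrom %in% names(ref$seqs))
    stop(sprintf("chromosome '%s' absent from reference", chrom))
  L <- as.double(length(ref$seqs[[chrom]]))
  if (start < 0 || end > L || start >= end)
    stop(sprintf("interval [%s,%s) out of bounds for %s (length %s)",
                 format(start), format(end), chrom, format(L)))
  s <- Biostrings::subseq(ref$seqs[[chrom]], start = start + 1, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Fetch the slice covered by a `genomic_interval`
#' @param ref a `ref_store`
#' @param interval a `genomic_interval` (its strand controls orientation)
#' @return a character string of length `gi_length(interval)`
#' @export
ref_fetch_interval <- function(ref, interval) {
  ref_fetch(ref, interval$chrom, interval$start, interval$end,
            interval$strand)
}

# assign plain (+ strand) bases over [start, start+nchar(value)) — used by
# the simulator when planting signatures
ref_assign <- function(ref, chrom, start, value) {
  n <- nchar(value)
  Biostrings::subseq(ref$seqs[[chrom]], start = start + 1,
                     end = start + n) <- Biostrings::DNAString(value)
  ref
}

#' Read a reference FASTA into a store
#' @param path FASTA file path
#' @return a `ref_store`
#' @export
read_reference_fasta <- function(path) {
  ref_store(Biostrings::readDNAStringSet(path))
}

#' Write a reference store to FASTA
#' @param ref a `ref_store`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref$seqs, path)
  invisible(path)
}
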