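# shared low-level helpers

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a plain character string
#'
#' N is complemented to N; input must be A/C/G/T/N.
#' @param x a single nucleotide string
#' @return the reverse complement string
#' @keywords internal
revcomp_chr <- function(x) {
  stopifnot(length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1L]]),
        collapse = "")
}

# split a string into a character vector of single bases
str_chars <- function(x) {
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}

# longest common prefix length of two character vectors of bases;
# N never matches anything, including N
lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  ok <- a[seq_len(n)] == b[seq_len(n)] & a[seq_len(n)] != "N" &
    b[seq_len(n)] != "N"
  w <- which(!ok)
  if (length(w) == 0L) n else w[1L] - 1L
}

# run a block of code with a private, seeded RNG stream, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# derive a child seed from a base seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  (as.double(seed) * 1103L + as.double(k) * 12821L) %% 2147483647
}

# format an output header line set for TSV writers
tsv_header <- function(seed = NULL, params = NULL, extra = character(0)) {
  ver <- as.character(utils::packageVersion("jctsig"))
  h <- sprintf("# jctsig %s", ver)
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", format(seed)))
  if (!is.null(params)) h <- c(h, sprintf("# params: %s", params_fingerprint(params)))
  c(h, extra)
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv_table <- function(path, colClasses = NA) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = colClasses)
}
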