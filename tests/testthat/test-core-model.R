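test_that("printed coordinate pairs keep the published length arithmetic", {
  x <- parse_interval("chrX: 102,778,586-102,779,195")
  expect_equal(gi_length(x), 609)
  expect_equal(format_interval(x), "chrX: 102,778,586-102,779,195")
  y <- parse_interval("ChrX: 99,762,680-104,246,638")
  expect_equal(gi_length(y), 4483958)
})

test_that("interval construction validates its inputs", {
  expect_error(gi("", 1, 2), "non-empty")
  expect_error(gi("chr1", 10, 10), "start")
  expect_error(gi("chr1", 10, 5), "start")
  expect_error(gi("chr1", 1, 2, strand = "?"), "strand")
})

test_that("reference store lookup is oriented and bounds-checked", {
  ref <- ref_store(c(c1 = "ACGTACGTTA"))
  expect_equal(ref_fetch(ref, "c1", 0, 4), "ACGT")
  expect_equal(ref_fetch(ref, "c1", 2, 8), "GTACGT")
  expect_equal(ref_fetch(ref, "c1", 2, 8, "-"), revcomp_chr("GTACGT"))
  expect_equal(nchar(ref_fetch(ref, "c1", 3, 9)), 6)
  expect_error(ref_fetch(ref, "c1", 5, 12), "out of bounds")
  expect_error(ref_fetch(ref, "nope", 0, 2), "nope")
})

test_that("FASTA round-trips through the store", {
  ref <- simulate_reference(1200, 0.5, seed = 4, chrom = "toy")
  fa <- tempfile(fileext = ".fa")
  write_reference_fasta(ref, fa)
  back <- read_reference_fasta(fa)
  expect_equal(ref_fetch(back, "toy", 0, 1200), ref_fetch(ref, "toy", 0, 1200))
})

make_parse_fixture <- function(seed = 21) {
  set.seed(seed)
  s1 <- rand_dna(600)
  s2 <- rand_dna(600)
  ref_store(c(c1 = s1, c2 = s2))
}

test_that("a read that is an exact substrate concatenation parses cleanly", {
  ref <- make_parse_fixture()
  prox <- gi("c1", 50, 200)
  dist <- gi("c2", 300, 450)
  read <- paste0(ref_fetch_interval(ref, prox), ref_fetch_interval(ref, dist))
  j <- junction("j1", "i1", read, prox, dist, ref = ref)
  expect_equal(j$insertion, "")
  expect_gte(j$prefix_len, 150)
  expect_gte(j$suffix_len, 150)
  expect_equal(j$anchor, j$prefix_len)
  expect_equal(j$overlap, j$prefix_len + j$suffix_len - nchar(read))
})

test_that("read spans supported by neither substrate become the insertion", {
  ref <- make_parse_fixture()
  prox <- gi("c1", 50, 200)
  dist <- gi("c2", 300, 450)
  pw <- ref_fetch_interval(ref, prox)
  dw <- ref_fetch_interval(ref, dist)
  # five inserted bases whose ends cannot extend either exact mapping
  cont <- ref_fetch(ref, "c1", 200, 201)          # proximal continuation
  prev <- ref_fetch(ref, "c2", 299, 300)          # base before the distal start
  ins <- c(setdiff(c("A", "C", "G", "T"), cont)[1], "A", "C",
           "G", setdiff(c("A", "C", "G", "T"), prev)[1])
  read <- paste0(pw, paste(ins, collapse = ""), dw)
  j <- junction("j2", "i1", read, prox, dist, ref = ref)
  expect_equal(nchar(j$insertion), 5)
  expect_equal(j$prefix_len, 150)
  expect_equal(j$suffix_len, 150)
})

test_that("minus-strand substrates are reverse-complemented before matching", {
  ref <- make_parse_fixture()
  prox <- gi("c1", 50, 200, strand = "-")
  dist <- gi("c2", 300, 450)
  read <- paste0(revcomp_chr(ref_fetch(ref, "c1", 50, 200)),
                 ref_fetch_interval(ref, dist))
  j <- junction("j3", "i1", read, prox, dist, ref = ref)
  expect_gte(j$prefix_len, 150)
  expect_equal(j$insertion, "")
})

test_that("junction tables round-trip through TSV", {
  ref <- make_parse_fixture()
  js <- list(
    junction("jA", "i1",
             paste0(ref_fetch(ref, "c1", 50, 200),
                    ref_fetch(ref, "c2", 300, 450)),
             gi("c1", 50, 200), gi("c2", 300, 450), ref = ref),
    junction("jB", "i2",
             paste0(revcomp_chr(ref_fetch(ref, "c1", 100, 250)),
                    ref_fetch(ref, "c2", 10, 160)),
             gi("c1", 100, 250, strand = "-"), gi("c2", 10, 160), ref = ref))
  path <- tempfile(fileext = ".tsv")
  write_junction_table(js, path, seed = 1)
  back <- read_junction_table(path, ref)
  expect_equal(length(back), 2)
  for (k in 1:2) {
    expect_equal(back[[k]]$read, js[[k]]$read)
    expect_equal(back[[k]]$proximal, js[[k]]$proximal)
    expect_equal(back[[k]]$distal, js[[k]]$distal)
    expect_equal(back[[k]]$anchor, js[[k]]$anchor)
  }
})

test_that("junction tables reject malformed input loudly", {
  ref <- make_parse_fixture()
  df <- data.frame(junction_id = "x", individual_id = "y", read = "ACGT",
                   prox_chrom = "c1", prox_start = "oops", prox_end = "200",
                   prox_strand = "+", dist_chrom = "c2", dist_start = "1",
                   dist_end = "5", dist_strand = "+")
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_junction_table(path, ref), "row 1")
  df$prox_start <- "10"; df$dist_chrom <- "c9"
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_junction_table(path, ref), "c9")
})

test_that("substrate windows are centred, truncated and oriented correctly", {
  set.seed(31)
  ref <- ref_store(c(big = rand_dna(10000)))
  j <- junction("jw", "i", paste0(ref_fetch(ref, "big", 4850, 5000),
                                  ref_fetch(ref, "big", 7000, 7150)),
                gi("big", 4850, 5000), gi("big", 7000, 7150), ref = ref)
  sp <- extract_substrate_pair(j, ref)
  expect_equal(nchar(sp$proximal_window), 300)
  expect_equal(nchar(sp$distal_window), 300)
  expect_equal(sp$anchor_col, 150)
  expect_false(sp$truncated)

  # proximal break 40 bp from the contig start: window shortened, flagged
  j2 <- junction("jt", "i", paste0(ref_fetch(ref, "big", 0, 40),
                                   ref_fetch(ref, "big", 7000, 7150)),
                 gi("big", 0, 40), gi("big", 7000, 7150), ref = ref)
  sp2 <- extract_substrate_pair(j2, ref)
  expect_equal(nchar(sp2$proximal_window), 190)
  expect_equal(sp2$anchor_col, 40)
  expect_true(sp2$truncated)
})

test_that("an inverted distal substrate window is the reverse complement", {
  toy <- "ACGTTGCAAGGTCCATAGGC"                       # 20 bp toy contig
  ref <- ref_store(c(t1 = toy))
  p <- signature_params(flank_window = 5)
  j <- junction("ji", "i", strrep("A", 10), gi("t1", 2, 7),
                gi("t1", 8, 13, strand = "-"), params = p)
  sp <- extract_substrate_pair(j, ref, p)
  # distal break is the oriented 5' start = interval end (13); window is
  # the reverse complement of the forward slice [8, 18)
  expect_equal(sp$distal_window, revcomp_chr(substr(toy, 9, 18)))
  expect_equal(sp$anchor_col, 5)
})
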