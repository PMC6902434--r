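test_that("the global aligner matches the reference dynamic program", {
  set.seed(12)
  for (t in 1:300) {
    a <- rand_dna(sample(1:30, 1))
    b <- rand_dna(sample(1:30, 1))
    res <- nw_align(a, b)
    expect_equal(res$score, oracle_nw_score(a, b))
    # removing gaps recovers the inputs
    expect_equal(gsub("-", "", res$a, fixed = TRUE), a)
    expect_equal(gsub("-", "", res$b, fixed = TRUE), b)
    expect_equal(nchar(res$a), nchar(res$b))
  }
})

test_that("alignment score is symmetric under input swap", {
  set.seed(13)
  for (t in 1:50) {
    a <- rand_dna(sample(5:25, 1)); b <- rand_dna(sample(5:25, 1))
    expect_equal(nw_align(a, b)$score, nw_align(b, a)$score)
  }
})

test_that("a single deleted base yields exactly one 1-column gap", {
  a <- "ACGTACATGCGT"
  b <- paste0(substr(a, 1, 5), substr(a, 7, 12))
  res <- nw_align(a, b)
  gaps <- gregexpr("-+", res$b)[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 1L)
  expect_false(grepl("-", res$a, fixed = TRUE))
})

test_that("anchored alignment keeps the signature block column-aligned", {
  ref <- simulate_reference(5000, 0.41, seed = 81)
  res <- plant_junction(ref, list(category = "microhomeology", mhe_len = 12,
                                  mhe_variant = "pure_left"), seed = 17)
  sp <- extract_substrate_pair(res$junction, res$ref)
  mh <- detect_microhomology(sp)
  mhe <- detect_microhomeology(sp, mh)
  aln <- align_substrates(sp, mh, mhe)
  expect_equal(gsub("-", "", aln$aligned_proximal, fixed = TRUE),
               sp$proximal_window)
  expect_equal(gsub("-", "", aln$aligned_distal, fixed = TRUE),
               sp$distal_window)
  # the block columns carry the microhomeology alignment verbatim
  bc <- aln$block_cols
  expect_equal(substr(aln$aligned_proximal, bc[1], bc[2]), mhe$aligned_prox)
  expect_equal(substr(aln$aligned_distal, bc[1], bc[2]), mhe$aligned_dist)
  # the join-point column lies inside the block
  expect_gte(aln$anchor_col, bc[1] - 1)
  expect_lte(aln$anchor_col, bc[2])
})

test_that("identical windows align gap-free with similarity one everywhere", {
  set.seed(14)
  w <- rand_dna(200)
  sp <- substrate_pair(w, w, 100)
  aln <- align_substrates(sp)
  expect_false(grepl("-", aln$aligned_proximal, fixed = TRUE))
  prof <- windowed_similarity(aln)
  expect_true(all(prof$values == 1))
})

fake_alignment <- function(a, b, anchor = nchar(a) %/% 2, block = NULL) {
  structure(list(aligned_proximal = a, aligned_distal = b,
                 anchor_col = anchor, block_cols = block, score = 0,
                 junction_id = "toy"), class = "pairwise_alignment")
}

test_that("moving-window similarity follows its definition", {
  # strictly alternating match/mismatch -> 0.5 at every interior column
  a <- strrep("AC", 30)
  b <- strrep("AG", 30)
  prof <- windowed_similarity(fake_alignment(a, b))
  expect_true(all(abs(prof$values[15:45] - 0.5) < 1e-12))
  # a window of only gap columns yields the gap marker
  a2 <- paste0(strrep("A", 30), strrep("-", 30), strrep("C", 30))
  b2 <- paste0(strrep("A", 30), strrep("G", 30), strrep("C", 30))
  prof2 <- windowed_similarity(fake_alignment(a2, b2))
  expect_true(all(is.na(prof2$values[41:50])))
  expect_true(all(is.na(prof2$prox_base[31:60])))  # gap marker on the base
  # the "all columns" denominator counts gaps against the window
  p_all <- signature_params(similarity_denominator = "all")
  prof3 <- windowed_similarity(fake_alignment(a2, b2), p_all)
  expect_equal(prof3$values[1], 1)
  expect_lt(prof3$values[25], 1)
})

test_that("windows inside an exact microhomology block score exactly one", {
  ref <- simulate_reference(5000, 0.41, seed = 91)
  res <- plant_junction(ref, list(category = "microhomology", mh_len = 9),
                        seed = 19)
  sp <- extract_substrate_pair(res$junction, res$ref)
  mh <- detect_microhomology(sp)
  aln <- align_substrates(sp, mh, detect_microhomeology(sp, mh))
  prof <- windowed_similarity(aln, signature_params(similarity_window = 5))
  bc <- aln$block_cols
  inner <- (bc[1] + 2):(bc[2] - 2)
  expect_true(all(prof$values[inner] == 1))
})

test_that("similarity is invariant under joint reverse complement", {
  # substitutions only and heavy enough (identity below the segment
  # cutoff, mismatches flanking the anchor) that the gap-free diagonal
  # is the unique optimal alignment with no centred block
  set.seed(15)
  p <- chars(rand_dna(80))
  d <- p
  mm <- unique(c(40L, 41L, sample(seq_along(p), 30)))
  d[mm] <- vapply(p[mm], function(x)
    sample(setdiff(BASES, x), 1), character(1))
  sp1 <- substrate_pair(paste(p, collapse = ""), paste(d, collapse = ""), 40)
  sp2 <- substrate_pair(revcomp_chr(sp1$proximal_window),
                        revcomp_chr(sp1$distal_window), 40)
  v1 <- windowed_similarity(align_substrates(sp1))$values
  v2 <- windowed_similarity(align_substrates(sp2))$values
  # an even window (20 columns: 10 left, 9 right of centre) mirrors onto
  # the neighbouring column, so the reversed profile is offset by one
  expect_equal(v2[-1], rev(v1)[-length(v1)])
})

fake_profile <- function(value, n = 320, anchor = 160) {
  structure(list(junction_id = "fp", group = NA_character_,
                 values = rep(value, n),
                 prox_base = rep(value, n), dist_base = rep(value, n),
                 prox_gap = rep(FALSE, n), dist_gap = rep(FALSE, n),
                 anchor_col = anchor, block_cols = NULL),
            class = "similarity_profile")
}

test_that("aggregation is the identity on constant profiles", {
  entries <- list(list(profile = fake_profile(1), group = "blunt",
                       base = "proximal"),
                  list(profile = fake_profile(1), group = "blunt",
                       base = "distal"))
  agg <- suppressWarnings(aggregate_by_group(entries))
  b <- agg[agg$group == "blunt", ]
  expect_true(all(b$mean == 1))
  expect_true(all(b$n == 2))
})

test_that("aggregation averages and is permutation-invariant", {
  e1 <- list(profile = fake_profile(0.2), group = "blunt", base = "proximal")
  e2 <- list(profile = fake_profile(0.6), group = "blunt", base = "proximal")
  a12 <- suppressWarnings(aggregate_by_group(list(e1, e2)))
  a21 <- suppressWarnings(aggregate_by_group(list(e2, e1)))
  expect_equal(a12, a21)
  b <- a12[a12$group == "blunt", ]
  expect_true(all(abs(b$mean - 0.4) < 1e-12))
})

test_that("empty groups are omitted with a warning, never NaN rows", {
  e <- list(list(profile = fake_profile(0.5), group = "blunt",
                 base = "proximal"))
  w <- testthat::capture_warnings(agg <- aggregate_by_group(e))
  expect_true(any(grepl("microhomology_only", w)))
  expect_false(any(is.nan(agg$mean)))
  expect_equal(unique(agg$group), "blunt")
})

test_that("heat-map matrices round-trip through TSV with gap markers", {
  a2 <- paste0(strrep("A", 40), strrep("-", 25), strrep("C", 40))
  b2 <- paste0(strrep("A", 40), strrep("G", 25), strrep("C", 40))
  prof <- windowed_similarity(fake_alignment(a2, b2))
  out <- file.path(tempdir(), "hmtest")
  render_heatmap(prof, out, image = FALSE)
  m <- read_heatmap_tsv(paste0(out, ".tsv"))
  expect_equal(unname(m["proximal_base", ]), prof$prox_base)
  expect_equal(unname(m["distal_base", ]), prof$dist_base)
  expect_true(all(is.na(m["proximal_base", 41:65])))
})
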