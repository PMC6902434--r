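test_that("reference simulation is seeded, GC-controlled and validated", {
  r1 <- simulate_reference(10000, 0.5, seed = 1)
  r2 <- simulate_reference(10000, 0.5, seed = 1)
  expect_equal(ref_fetch(r1, "chrS", 0, 10000), ref_fetch(r2, "chrS", 0, 10000))
  r3 <- simulate_reference(100000, 0.6, seed = 2)
  s <- strsplit(ref_fetch(r3, "chrS", 0, 100000), "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_gte(gc, 0.58)
  expect_lte(gc, 0.62)
  expect_error(simulate_reference(500, 0.5, seed = 3), "at least 1000")
})

test_that("planted junctions are deterministic for a fixed seed", {
  ref <- simulate_reference(5000, 0.41, seed = 8)
  a <- plant_junction(ref, list(category = "microhomeology"), seed = 42)
  b <- plant_junction(ref, list(category = "microhomeology"), seed = 42)
  expect_equal(a$junction$read, b$junction$read)
  expect_equal(a$truth, b$truth)
  expect_equal(ref_fetch(a$ref, "chrS", 0, 5000), ref_fetch(b$ref, "chrS", 0, 5000))
})

test_that("planted signatures are the unique maximal signature at the join", {
  ref <- simulate_reference(5000, 0.41, seed = 8)
  bl <- plant_junction(ref, list(category = "blunt"), seed = 5)
  sp <- extract_substrate_pair(bl$junction, bl$ref)
  expect_equal(detect_microhomology(sp)$length, 0L)
  expect_false(detect_microhomeology(sp)$present)

  mh6 <- plant_junction(ref, list(category = "microhomology", mh_len = 6),
                        seed = 6)
  sp6 <- extract_substrate_pair(mh6$junction, mh6$ref)
  # brute-force two-direction extension oracle
  expect_equal(oracle_microhomology(sp6), 6L)
  expect_equal(detect_microhomology(sp6)$length, 6L)

  mhe <- plant_junction(ref, list(category = "microhomeology", mhe_len = 12,
                                  mhe_identity = 0.75,
                                  mhe_variant = "pure_left"), seed = 7)
  spm <- extract_substrate_pair(mhe$junction, mhe$ref)
  call <- detect_microhomeology(spm)
  expect_true(call$present)
  expect_equal(call$length, 12L)
  # 0.75 identity over 12 columns = exactly 3 mismatches
  expect_equal(call$n_match, 9L)
  expect_lte(abs(call$identity - 0.75), 1 / 12)
  expect_equal(mhe$truth$planted_mhe_identity, 0.75)
})

test_that("unsatisfiable plant specifications fail loudly", {
  ref <- simulate_reference(5000, 0.41, seed = 8)
  expect_error(plant_junction(ref, list(category = "microhomeology",
                                        mhe_identity = 0.5), seed = 1),
               "identity")
  expect_error(plant_junction(ref, list(category = "microhomeology",
                                        mhe_len = 40), seed = 1), "length")
  expect_error(plant_junction(ref, list(category = "nonsense"), seed = 1),
               "supported")
})

test_that("a simple tandem duplication yields one head-to-tail junction", {
  ref <- simulate_reference(60000, 0.41, seed = 13, chrom = "chrT")
  rr <- simulate_rearrangement(ref, "DUP", seed = 3, individual_id = "d1")
  expect_equal(classify_pattern(rr$profile)$pattern, "DUP")
  expect_equal(length(rr$junctions), 1L)
  j <- rr$junctions[[1]]
  dup <- rr$profile$segments[rr$profile$segments$state == "DUP", ]
  expect_equal(j$proximal$end, dup$end)       # sequence ends at the dup end
  expect_equal(j$distal$start, dup$start)     # ... and re-enters at its start
  expect_equal(j$proximal$strand, "+")
  expect_equal(j$distal$strand, "+")
})

test_that("DUP-TRP-DUP is generated as the inverted-triplication structure", {
  ref <- simulate_reference(60000, 0.41, seed = 13, chrom = "chrT")
  rr <- simulate_rearrangement(ref, "DUP-TRP-DUP", seed = 4,
                               individual_id = "t1")
  expect_equal(classify_pattern(rr$profile)$pattern, "DUP-TRP-DUP")
  strands <- vapply(rr$junctions, function(j)
    paste0(j$proximal$strand, j$distal$strand), character(1))
  # one switch enters the triplication inverted, the second restores it
  expect_setequal(strands, c("+-", "-+"))
})

test_that("DUP-NML-DEL produces the expected copy-state sequence", {
  ref <- simulate_reference(60000, 0.41, seed = 13, chrom = "chrT")
  rr <- simulate_rearrangement(ref, "DUP-NML-DEL", seed = 5,
                               individual_id = "x1")
  expect_equal(classify_pattern(rr$profile)$pattern, "DUP-NML-DEL")
  expect_error(simulate_rearrangement(ref, "DUP-HEX", seed = 1), "supported")
})

state_copy <- c(DEL = 0, NML = 1, DUP = 2, TRP = 3, QUAD = 4)

test_that("replaying the plan reconstructs a haplotype matching the profile", {
  ref <- simulate_reference(60000, 0.41, seed = 19, chrom = "chrT")
  for (pat in c("DUP", "DUP-NML-DUP", "DUP-TRP-DUP", "DUP-NML-DEL",
                "DUP-QUAD-TRP", "DUP-NML-DUP-NML-DUP")) {
    # plant insertion-free signatures so junction reads are contiguous in
    # the derived haplotype (an insertion adds bases the piece plan does
    # not model; copy counts are unaffected either way)
    rr <- simulate_rearrangement(ref, pat, seed = 23, individual_id = "r",
                                 categories = rep("microhomology", 6))
    # per-base copy counts from the plan pieces equal the profile states
    segs <- rr$profile$segments
    for (k in seq_len(nrow(segs))) {
      mid <- floor((segs$start[k] + segs$end[k]) / 2)
      cov <- sum(vapply(rr$pieces, function(p)
        p$start <= mid && mid < p$end, logical(1)))
      expect_equal(cov, unname(state_copy[segs$state[k]]),
                   label = sprintf("%s segment %d copy count", pat, k))
    }
    # every junction read is a contiguous stretch of the derived haplotype
    hap <- paste(vapply(rr$pieces, function(p)
      ref_fetch(rr$ref, "chrT", p$start, p$end, p$strand), character(1)),
      collapse = "")
    for (j in rr$junctions)
      expect_true(grepl(j$read, hap, fixed = TRUE),
                  label = sprintf("%s junction %s in haplotype", pat,
                                  j$junction_id))
  }
})

test_that("junctions can be withheld as explicitly unresolved", {
  ref <- simulate_reference(60000, 0.41, seed = 19, chrom = "chrT")
  rr <- simulate_rearrangement(ref, "DUP-NML-DUP", seed = 29,
                               individual_id = "u1", drop_junctions = 2L)
  expect_equal(length(rr$junctions), 1L)
  expect_s3_class(rr$unresolved, "data.frame")
  expect_equal(rr$unresolved$status, "unresolved")
})

test_that("the cohort generator realises the requested mixtures exactly", {
  sim <- simulate_cohort(n_individuals = 20, seed = 77)
  pats <- table(sim$pattern_truth$pattern)
  expected <- jctsig:::apportion(jctsig:::pattern_spectrum, 20)
  names(expected) <- names(jctsig:::pattern_spectrum)
  expected <- expected[expected > 0]
  expect_equal(as.integer(pats[names(expected)]), unname(expected))
  expect_equal(sum(sim$pattern_truth$in_cluster),
               jctsig:::apportion(c(0.56, 0.44), 20)[1])
  # the truth table covers every junction
  expect_setequal(sim$truth$junction_id,
                  vapply(sim$junctions, function(j) j$junction_id, ""))
})

test_that("the isolated junction set spans all categories with annotations", {
  js <- simulate_junction_set(n = 60, seed = 31)
  tab <- table(js$truth$planted_category)
  expected <- jctsig:::apportion(jctsig:::joinpoint_spectrum, 60)
  names(expected) <- names(jctsig:::joinpoint_spectrum)
  expect_equal(as.integer(tab[names(expected)]), unname(expected))
  chim <- js$truth$planted_category %in%
    c("alu_alu_chimera", "line_line_chimera", "paralogous_repeat_other")
  expect_true(all(js$truth$junction_id[chim] %in%
                    sub("^(jct[0-9]+)$", "\\1", js$annotations$chrom)))
  # truth TSV round-trips
  path <- tempfile(fileext = ".tsv")
  write_truth_table(js$truth, path, seed = 31)
  back <- read_truth_table(path)
  expect_equal(nrow(back), nrow(js$truth))
  expect_equal(back$planted_category, js$truth$planted_category)
})
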