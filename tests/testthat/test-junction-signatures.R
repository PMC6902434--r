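# build a window pair where the distal window mismatches the proximal
# everywhere except at chosen offsets (offset -1 = base just 5' of the
# join); returns a substrate_pair
pair_with_matches <- function(match_offs, n = 60, anchor = 30,
                              prox = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- if (is.null(prox)) sample(BASES, n, replace = TRUE) else chars(prox)
  d <- vapply(p, function(x) sample(setdiff(BASES, x), 1), character(1))
  idx <- anchor + 1 + match_offs
  d[idx] <- p[idx]
  substrate_pair(paste(p, collapse = ""), paste(d, collapse = ""), anchor)
}

test_that("a join with immediate mismatches on both sides is blunt", {
  sp <- pair_with_matches(integer(0), seed = 1)
  mh <- detect_microhomology(sp)
  expect_equal(mh$length, 0L)
  expect_equal(mh$sequence, "")
})

test_that("a shared run across the join is reported with its sequence", {
  set.seed(2)
  p <- sample(BASES, 40, replace = TRUE)
  p[19:23] <- c("C", "C", "G", "G", "T")      # offsets -2..+2 around col 20
  sp <- pair_with_matches(-2:2, n = 40, anchor = 20,
                          prox = paste(p, collapse = ""))
  mh <- detect_microhomology(sp)
  expect_equal(mh$length, 5L)
  expect_equal(mh$sequence, "CCGGT")
  expect_equal(mh$left, 2L)
  expect_equal(mh$right, 3L)
})

test_that("microhomology equals the brute-force extension oracle", {
  set.seed(3)
  for (t in 1:2000) {
    n <- sample(10:60, 1)
    sp <- substrate_pair(rand_dna(n), rand_dna(n), sample(0:n, 1))
    expect_equal(detect_microhomology(sp)$length, oracle_microhomology(sp))
  }
})

test_that("N bases never match, even another N", {
  sp <- substrate_pair("AANCC", "AANCC", 2)
  expect_equal(detect_microhomology(sp)$length, 2L)  # run stops at the N
  sp2 <- substrate_pair("AANCC", "AANGC", 3)
  expect_equal(detect_microhomology(sp2)$length, 0L)
})

test_that("swapping substrates keeps microhomology and flips priming", {
  ref <- simulate_reference(5000, 0.41, seed = 41)
  res <- plant_junction(ref, list(category = "microhomeology", mhe_len = 10,
                                  mhe_variant = "pure_left"), seed = 11)
  sp <- extract_substrate_pair(res$junction, res$ref)
  # a true substrate swap views the junction from the other strand:
  # reverse-complement both windows and exchange their roles
  swapped <- substrate_pair(revcomp_chr(sp$distal_window),
                            revcomp_chr(sp$proximal_window),
                            nchar(sp$proximal_window) - sp$anchor_col)
  expect_equal(detect_microhomology(sp)$length,
               detect_microhomology(swapped)$length)
  a <- detect_microhomeology(sp)
  b <- detect_microhomeology(swapped)
  expect_equal(a$length, b$length)
  expect_equal(a$priming_side, "proximal")
  expect_equal(b$priming_side, "distal")
})

test_that("a perfect shared stretch is microhomology, never microhomeology", {
  sp <- pair_with_matches(-5:4, seed = 4)        # identical 10-bp stretch
  mh <- detect_microhomology(sp)
  expect_equal(mh$length, 10L)
  expect_false(detect_microhomeology(sp, mh)$present)
})

test_that("an imperfect 10-column block is called with its identity", {
  # block at offsets -10..-1, mismatches at -4 and -7, clean flanks
  sp <- pair_with_matches(setdiff(-10:-1, c(-4, -7)), seed = 5)
  call <- detect_microhomeology(sp)
  expect_true(call$present)
  expect_equal(call$length, 10L)
  expect_equal(call$n_match, 8L)
  expect_equal(call$identity, 0.8)
  expect_equal(call$priming_side, "proximal")
  expect_equal(call$gap_runs, integer(0))
})

test_that("a deletion in one substrate is bridged by a single short gap", {
  set.seed(6)
  x <- sample(BASES, 12, replace = TRUE)
  # distal window lacks the 5th base of the proximal stretch (away order)
  p <- sample(BASES, 60, replace = TRUE)
  d <- vapply(p, function(b) sample(setdiff(BASES, b), 1), character(1))
  p[(30 - 11):30] <- rev(x)                      # proximal: x away-order
  d[(30 - 10):30] <- rev(x[-5])                  # distal: x minus one base
  sp <- substrate_pair(paste(p, collapse = ""), paste(d, collapse = ""), 30)
  call <- detect_microhomeology(sp)
  exp <- oracle_mhe(sp)
  expect_true(call$present)
  expect_equal(call$length, exp$length)
  expect_equal(call$n_match, exp$n_match)
  expect_equal(call$gap_runs, 1L)
  expect_equal(nchar(call$aligned_prox), nchar(call$aligned_dist))
})

test_that("microhomeology detection equals the segment-enumeration oracle", {
  set.seed(7)
  for (t in 1:400) {
    n <- sample(c(20, 40, 60), 1)
    sp <- substrate_pair(rand_dna(n), rand_dna(n), n %/% 2)
    got <- detect_microhomeology(sp)
    exp <- oracle_mhe(sp)
    expect_equal(got$present, exp$present)
    expect_equal(got$length, exp$length)
    expect_equal(got$n_match, exp$n_match)
  }
})

test_that("the segment oracle itself matches full enumeration on tiny windows", {
  set.seed(8)
  for (t in 1:120) {
    sp <- substrate_pair(rand_dna(12), rand_dna(12), 6)
    expect_equal(oracle_mhe(sp), dfs_mhe(sp))
  }
})

test_that("chimeric repeat junctions are called from annotations", {
  ref <- simulate_reference(5000, 0.41, seed = 51)
  alu <- plant_junction(ref, list(category = "alu_alu_chimera",
                                  inverted = TRUE), seed = 2)
  expect_equal(call_chimeric_repeat(alu$junction, alu$annotations)$call,
               "alu_alu")
  expect_equal(call_chimeric_repeat(alu$junction, alu$annotations)$orientation,
               "inverted")
  line <- plant_junction(ref, list(category = "line_line_chimera"), seed = 3)
  cc <- call_chimeric_repeat(line$junction, line$annotations)
  expect_equal(cc$call, "line_line")
  expect_setequal(c(cc$proximal_element, cc$distal_element),
                  c("L1PA5", "L1PA3"))
  # one breakpoint inside the element, the other in unique sequence
  half <- line$annotations[1, , drop = FALSE]
  expect_equal(call_chimeric_repeat(line$junction, half)$call, "none")
  expect_true(call_chimeric_repeat(line$junction, NULL)$no_annotation)
})

test_that("category precedence puts insertions above micro-signatures", {
  # junction with a 3-bp insertion AND a 4-bp microhomology at the join
  set.seed(9)
  s <- rand_dna(1200)
  ref <- ref_store(c(cz = s))
  a <- 300; b <- 800
  base <- chars(s)
  # distal window mismatches the proximal one except a 4-bp run (-2..+1)
  for (o in -40:39) {
    pb <- base[a + 1 + o]
    base[b + 1 + o] <- if (o %in% -2:1) pb else
      sample(setdiff(BASES, pb), 1)
  }
  s <- paste(base, collapse = "")
  ref <- ref_store(c(cz = s))
  cont <- substr(s, a + 1, a + 1)
  prev <- substr(s, b, b)
  ins <- paste0(setdiff(BASES, cont)[1], "A", setdiff(BASES, prev)[1])
  read <- paste0(ref_fetch(ref, "cz", a - 150, a), ins,
                 ref_fetch(ref, "cz", b, b + 150))
  j <- junction("prec", "i", read, gi("cz", a - 150, a), gi("cz", b, b + 150),
                ref = ref)
  cl <- classify_joinpoint(j, ref = ref)
  expect_equal(cl$category, "insertion")
  expect_equal(cl$insertion_len, 3L)
  expect_equal(cl$insertion_class, "small")
  expect_equal(cl$mh$length, 4L)               # measurement retained
})

test_that("a join with both signatures is counted as microhomeology", {
  ref <- simulate_reference(5000, 0.41, seed = 61)
  res <- plant_junction(ref, list(category = "microhomeology", mhe_len = 12,
                                  mhe_variant = "with_mh_left"), seed = 13)
  cl <- classify_joinpoint(res$junction, ref = res$ref)
  expect_equal(cl$category, "microhomeology")
  expect_true(cl$mhe$contains_microhomology)
  expect_equal(cl$mhe$mh_position, "right_end")
  expect_gte(cl$mh$length, 2L)
})

test_that("blunt concatenations and 1-bp matches stay distinct categories", {
  ref <- simulate_reference(5000, 0.41, seed = 71)
  bl <- plant_junction(ref, list(category = "blunt"), seed = 4)
  expect_equal(classify_joinpoint(bl$junction, ref = bl$ref)$category, "blunt")
  ob <- plant_junction(ref, list(category = "one_bp_match"), seed = 5)
  expect_equal(classify_joinpoint(ob$junction, ref = ob$ref)$category,
               "one_bp_match")
})

test_that("category labels match the published table rows", {
  expect_equal(unname(jctsig:::category_labels["microhomology"]),
               "Microhomology > 2 bp")
  expect_equal(unname(jctsig:::category_labels["one_bp_match"]),
               "Join-points with 1 bp match")
  expect_setequal(names(jctsig:::category_labels),
                  jctsig:::joinpoint_categories)
})
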