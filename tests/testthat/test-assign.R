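test_that("align_to_precursor reports the best stratum only", {
  set.seed(41)
  ref <- random_dna(120)
  tag <- substr(ref, 31, 52)
  a <- align_to_precursor(tag, ref)
  expect_equal(a$start, 30L)
  expect_equal(a$mm, 0L)
  expect_equal(a$mm_pos, "")

  # last base substituted: one 1-mm alignment with mismatch at len-1
  tag1 <- paste0(substr(tag, 1, 21), c(A = "C", C = "G", G = "T", T = "A")[[
    substr(tag, 22, 22)]])
  a1 <- align_to_precursor(tag1, ref)
  expect_equal(a1$mm, 1L)
  expect_equal(a1$mm_pos, "21")

  # a 0-mm placement suppresses 1/2-mm placements elsewhere
  alt <- c(A = "C", C = "G", G = "T", T = "A")[[substr(ref, 52, 52)]]
  ref2 <- paste0(ref, substr(ref, 31, 51), alt)  # 1-mm copy at the 3' end
  a2 <- align_to_precursor(tag, ref2)
  expect_equal(a2$start, 30L)
  expect_equal(nrow(a2), 1L)

  # longer than the reference
  expect_equal(nrow(align_to_precursor(random_dna(30), random_dna(20))), 0L)
})

test_that("align_to_precursor matches the brute-force Hamming oracle", {
  set.seed(42)
  for (i in 1:60) {
    ref <- random_dna(sample(60:140, 1))
    tag <- if (i %% 2 == 0) random_dna(sample(16:26, 1)) else {
      l <- sample(16:26, 1)
      o <- sample(1:(nchar(ref) - l + 1), 1)
      s <- substr(ref, o, o + l - 1)
      nmm <- sample(0:2, 1)
      for (p in sample(l, nmm)) {
        substr(s, p, p) <- c(A = "C", C = "G", G = "T", T = "A")[[
          substr(s, p, p)]]
      }
      s
    }
    got <- align_to_precursor(tag, ref)
    oracle <- oracle_hamming_scan(tag, ref)
    if (!nrow(oracle)) {
      expect_equal(nrow(got), 0L)
    } else {
      best <- min(oracle$mm)
      expect_equal(got$start, oracle$start[oracle$mm == best])
      expect_true(all(got$mm == best))
    }
  }
})

test_that("2-mm alignments survive only with both mismatches at the 3' end", {
  alns <- data.frame(start = 0L, end = 22L, mm = c(2L, 2L, 1L, 0L),
                     mm_pos = c("20,21", "0,21", "5", ""),
                     stringsAsFactors = FALSE)
  expect_equal(filter_two_mismatch_3prime(alns), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("build_blocks clusters pile-ups and keeps adjacent products apart", {
  # two pile-ups 40 nt apart -> two blocks at the modal intervals
  alns <- data.frame(
    seq = c("a", "b", "c", "d"),
    count = c(100L, 30L, 80L, 10L),
    start = c(30L, 32L, 70L, 71L),
    end = c(52L, 52L, 92L, 93L), stringsAsFactors = FALSE)
  b <- build_blocks(alns)
  expect_equal(nrow(b), 2L)
  expect_equal(b$start, c(30L, 70L))
  expect_equal(b$rep_seq, c("a", "c"))
  expect_equal(b$total_count, c(130L, 90L))
  expect_equal(attr(b, "members"), c(1L, 1L, 2L, 2L))

  # single tag
  b1 <- build_blocks(alns[1, ])
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$start, b1$end), c(30L, 52L))

  # staggered 5' ends within 3 nt of a dominant tag join its block;
  # representative = the dominant tag (exhaustive membership check)
  set.seed(43)
  stag <- data.frame(
    seq = sprintf("s%d", 1:5),
    count = c(500L, 40L, 30L, 20L, 10L),
    start = c(50L, 47L, 48L, 51L, 53L),
    end = c(72L, 69L, 70L, 73L, 75L), stringsAsFactors = FALSE)
  bs <- build_blocks(stag)
  expect_equal(nrow(bs), 1L)
  expect_equal(bs$rep_seq, "s1")
  ov <- pmin(stag$end, 72L) - pmax(stag$start, 50L)
  expect_true(all(ov > 0.5 * (stag$end - stag$start)))

  # a moR overlapping the miR seed by 2 nt stays its own block
  mor <- data.frame(seq = c("mir", "mor"), count = c(400L, 50L),
                    start = c(72L, 92L), end = c(94L, 112L),
                    stringsAsFactors = FALSE)
  bm <- build_blocks(mor)
  expect_equal(nrow(bm), 2L)

  # blocks never overlap by more than half of the smaller one
  set.seed(44)
  rnd <- data.frame(seq = sprintf("t%d", 1:60),
                    count = sample(1:500, 60, replace = TRUE),
                    start = sample(0:100, 60, replace = TRUE),
                    stringsAsFactors = FALSE)
  rnd$end <- rnd$start + sample(18:25, 60, replace = TRUE)
  br <- build_blocks(rnd)
  if (nrow(br) > 1) {
    for (i in 1:(nrow(br) - 1)) for (j in (i + 1):nrow(br)) {
      ov <- min(br$end[i], br$end[j]) - max(br$start[i], br$start[j])
      smaller <- min(br$end[i] - br$start[i], br$end[j] - br$start[j])
      expect_lte(ov, 0.5 * smaller)
    }
  }
})

# A deterministic hairpin world for finalize/assign tests.
hp_world <- function() {
  hp <- make_hairpin(seed = 45L, mature_arm = "3p", name = "sim-mir-421")
  ext <- structure(list(id = hp$id, name = hp$name, seq = hp$ext_seq,
                        chrom = "c1", strand = "+", gstart_ext = 0L,
                        flank5 = hp$flank, flank3 = hp$flank,
                        prec_local = hp$prec_local,
                        matures = data.frame(id = hp$matures$id,
                                             name = hp$matures$name,
                                             start = hp$matures$start,
                                             end = hp$matures$end,
                                             stringsAsFactors = FALSE)),
                   class = "extended_precursor")
  list(hp = hp, ext = ext, fold = hp$fold, truth = hp$truth)
}

truth_blocks <- function(w, counts) {
  tr <- w$truth
  data.frame(block_id = seq_len(nrow(tr)), start = tr$start, end = tr$end,
             rep_seq = tr$seq, total_count = counts,
             n_members = 1L, stringsAsFactors = FALSE)
}

test_that("finalize_srnas calls miR, star new_miR, moRs and loop", {
  w <- hp_world()
  blocks <- truth_blocks(w, c(120L, 500L, 50L, 40L, 25L))
  defs <- finalize_srnas(w$ext, w$fold, blocks, assign_params())
  expect_setequal(defs$name, c("miR-421-3p", "miR-421-5p", "moR-421-5p",
                               "moR-421-3p", "loop-421"))
  expect_equal(defs$class[defs$name == "miR-421-3p"], "mir")
  expect_equal(defs$class[defs$name == "miR-421-5p"], "new_mir")
  expect_equal(defs$class[defs$name == "moR-421-5p"], "mor")
  # per-precursor cardinality: <= 4 miR/moR products + <= 1 loop
  expect_lte(sum(defs$class != "loop"), 4L)
  expect_lte(sum(defs$class == "loop"), 1L)
  # coordinates: annotated miR keeps annotation, moR is block-driven
  tr <- w$truth
  for (nm in defs$name) {
    expect_equal(defs$start[defs$name == nm], tr$start[tr$name == nm])
    expect_equal(defs$end[defs$name == nm], tr$end[tr$name == nm])
  }
})

test_that("finalize_srnas drops short moR blocks (MIN_MORNA_LEN)", {
  w <- hp_world()
  blocks <- truth_blocks(w, c(120L, 500L, 50L, 40L, 25L))
  i <- which(w$truth$name == "moR-421-5p")
  blocks$start[i] <- blocks$end[i] - 15L  # 15 nt block
  defs15 <- finalize_srnas(w$ext, w$fold, blocks,
                           assign_params(min_morna_len = 16L))
  expect_false("moR-421-5p" %in% defs15$name)
  defs_sens <- finalize_srnas(w$ext, w$fold, blocks,
                              assign_params(min_morna_len = 15L))
  expect_true("moR-421-5p" %in% defs_sens$name)
})

test_that("mor_sequence_filter removes sequence-sharing moRs conservatively", {
  defs <- data.frame(
    precursor_id = c("p1", "p1", "p2"), precursor_name = "x",
    class = c("mir", "mor", "mor"), arm = c("3p", "5p", "5p"),
    start = 0L, end = 22L,
    name = c("miR-x-3p", "moR-x-5p", "moR-y-5p"),
    seq = c("ACGTACGTACGTACGTACGTAC",
            "GTACGTACGTACGTACGTA",    # substring of the miR
            "TTTTTGGGGGCCCCCAAAAA"),
    support_count = 10L, stringsAsFactors = FALSE)
  cons <- mor_sequence_filter(defs, "conservative")
  expect_false("moR-x-5p" %in% cons$name)
  expect_true("moR-y-5p" %in% cons$name)
  perm <- mor_sequence_filter(defs, "permissive")
  expect_equal(perm, defs)
  # sharing only a few terminal bases is kept in both modes
  defs$seq[2] <- paste0("TTTTTTTTTTTTTTTTT", substr(defs$seq[1], 1, 5))
  expect_true("moR-x-5p" %in% mor_sequence_filter(defs, "conservative")$name)
})

test_that("assign_alignment enforces the overhang and precedence rules", {
  defs <- data.frame(
    precursor_id = "p1", precursor_name = "x",
    class = c("mir", "mor"), arm = c("3p", "3p"),
    start = c(72L, 92L), end = c(94L, 112L),
    name = c("miR-x-3p", "moR-x-3p"), seq = "N",
    support_count = 10L, stringsAsFactors = FALSE)
  p3 <- assign_params(allowed_overhang = 3L)
  p4 <- assign_params(allowed_overhang = 4L)
  # canonical moR +/- 0
  expect_equal(assign_alignment(c(92L, 112L), defs, p3), 2L)
  # read extending 4 nt past the moR 5' end: unassigned at 3, assigned at 4
  expect_true(is.na(assign_alignment(c(88L, 112L), defs, p3)))
  expect_equal(assign_alignment(c(88L, 112L), defs, p4), 2L)
  # monotonicity: enlarging the overhang never unassigns
  set.seed(46)
  for (i in 1:50) {
    aln <- c(90L, 110L) + sample(-5:5, 2, replace = TRUE)
    if (aln[2] <= aln[1]) next
    a3 <- assign_alignment(aln, defs, p3)
    a4 <- assign_alignment(aln, defs, p4)
    if (!is.na(a3)) expect_false(is.na(a4))
  }
  # precedence on a perfect tie: mir beats mor
  tie <- data.frame(
    precursor_id = "p1", precursor_name = "x",
    class = c("mor", "mir"), arm = c("3p", "3p"),
    start = c(80L, 80L), end = c(102L, 102L),
    name = c("moR", "miR"), seq = "N", support_count = 1L,
    stringsAsFactors = FALSE)
  hit <- assign_alignment(c(80L, 102L), tie, p3)
  expect_equal(tie$class[hit], "mir")
})
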