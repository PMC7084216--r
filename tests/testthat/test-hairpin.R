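test_that("extend_precursor slices genome with flanks and truncation", {
  set.seed(31)
  chrom_seq <- random_dna(400)
  genome <- Biostrings::DNAStringSet(c(c1 = chrom_seq))
  prec <- data.frame(id = "p1", name = "p1", chrom = "c1", start = 100L,
                     end = 180L, strand = "+", stringsAsFactors = FALSE)
  ext <- extend_precursor(prec, genome)
  expect_equal(nchar(ext$seq), 140L)
  expect_equal(ext$flank5, 30L)
  expect_equal(ext$flank3, 30L)
  expect_equal(ext$seq, substr(chrom_seq, 71, 210))
  expect_equal(ext$prec_local, c(30L, 110L))

  # truncation at the contig start
  prec$start <- 10L; prec$end <- 90L
  ext2 <- extend_precursor(prec, genome)
  expect_equal(ext2$flank5, 10L)
  expect_equal(nchar(ext2$seq), 120L)

  # minus strand: local 0 is the transcript 5' end
  prec <- data.frame(id = "p2", name = "p2", chrom = "c1", start = 100L,
                     end = 180L, strand = "-", stringsAsFactors = FALSE)
  extm <- extend_precursor(prec, genome)
  expect_equal(extm$seq, revcomp(substr(chrom_seq, 71, 210)))

  # unknown chromosome
  prec$chrom <- "nope"
  expect_error(extend_precursor(prec, genome), "absent")
})

test_that("mature local/genomic round-trip is the identity on both strands", {
  set.seed(32)
  genome <- Biostrings::DNAStringSet(c(c1 = random_dna(500)))
  for (strand in c("+", "-")) {
    prec <- data.frame(id = "p", name = "p", chrom = "c1", start = 150L,
                       end = 260L, strand = strand, stringsAsFactors = FALSE)
    matures <- data.frame(id = c("m1", "m2"), name = c("m1", "m2"),
                          start = c(155L, 230L), end = c(177L, 252L),
                          stringsAsFactors = FALSE)
    ext <- extend_precursor(prec, genome, matures)
    for (i in 1:2) {
      g <- local_to_genomic(ext, ext$matures$start[i], ext$matures$end[i])
      expect_equal(g, c(matures$start[i], matures$end[i]))
    }
  }
})

test_that("fold_hairpin maximizes pairs and matches the example", {
  f <- fold_hairpin("GGGGAAAACCCC")
  expect_equal(f$db, "((((....))))")
  expect_equal(sum(!is.na(f$pairs)) / 2, 4)
  expect_equal(f$pairs[1], 12L)
  # no complementary bases -> all dots
  expect_equal(fold_hairpin("AAAAAAAAAA")$db, "..........")
  expect_error(fold_hairpin("ACGTACG"), "too short")
})

test_that("external dot-bracket mode validates invariants", {
  expect_error(fold_hairpin("ACGTAC", structure = "((..))"), "loop")
  expect_error(fold_hairpin("ACGTACGTAC", structure = "((......)"),
               "length differs")
  expect_error(parse_dot_bracket("((......)"), "unbalanced")
  expect_error(parse_dot_bracket(".....)"), "unbalanced")
  expect_error(parse_dot_bracket("..[].."), "invalid")
  f <- fold_hairpin("GGGGAAAACCCC", structure = "((((....))))")
  expect_equal(f$pairs[2], 11L)
})

test_that("fold agrees with the recurrence oracle on short sequences", {
  set.seed(33)
  for (i in 1:40) {
    s <- random_dna(sample(10:18, 1))
    f <- fold_hairpin(s)
    expect_equal(sum(!is.na(f$pairs)) / 2, oracle_max_pairs(s), info = s)
  }
})

test_that("project_star reproduces duplex geometry on perfect hairpins", {
  stem <- 40L; loop <- 10L; flank <- 25L
  f <- perfect_fold(stem, loop, flank)
  n <- nchar(f$db)
  p0 <- function(x) { # analytic perfect partner, 0-based
    ifelse(x < flank + stem,
           flank + 2L * stem + loop - 1L - (x - flank),
           flank + stem - 1L - (x - (flank + stem + loop)))
  }
  set.seed(34)
  for (i in 1:25) {
    arm <- sample(c("5p", "3p"), 1)
    len <- sample(18:24, 1)
    a <- if (arm == "5p") flank + sample(0:(stem - len), 1) else
      flank + stem + loop + sample(0:(stem - len), 1)
    mature <- c(a, a + len)
    star <- project_star(mature, f)
    analytic <- c(p0(mature[2] - 1L) + 2L, p0(mature[1]) + 3L)
    expect_equal(star, as.integer(pmin(pmax(analytic, 0L), n)))
    expect_equal(star[2] - star[1], len)
  }
})

test_that("project_star refuses unpaired matures and mature overlaps", {
  f <- perfect_fold(20, 8, 30)
  # mature fully in the 5' flank: unpaired -> no star
  expect_null(project_star(c(2L, 24L), f))
  # mature on the 5' arm projects onto the 3' arm; veto if an annotated
  # mature already occupies it
  mature <- c(30L, 50L)
  star <- project_star(mature, f)
  expect_false(is.null(star))
  occupied <- data.frame(start = star[1], end = star[2])
  expect_null(project_star(mature, f, matures = occupied))
  # a <= 3 nt overlap is tolerated
  shifted <- data.frame(start = star[2] - 3L, end = star[2] + 19L)
  expect_false(is.null(project_star(mature, f, matures = shifted)))
})

test_that("star interval spans bulges in the star arm", {
  # hand-built hairpin: 5' arm pairs the 3' arm around a 3-nt bulge
  db <- paste0("((((((((", "...", "))))", "...", "))))")
  pairs <- parse_dot_bracket(db)
  f <- structure(list(db = db, pairs = pairs), class = "fold_result")
  star <- project_star(c(0L, 8L), f, overhang = 0L)
  # partners span positions 11..21 inclusive -> [11, 22): includes the bulge
  expect_equal(star, c(11L, 22L))
})

test_that("mor_geometry builds the three windows", {
  g <- mor_geometry(c(30L, 52L), c(72L, 94L), 124L)
  expect_equal(g$mor5p_window, c(0L, 33L))
  expect_equal(g$mor3p_window, c(91L, 124L))
  expect_equal(g$loop, c(52L, 72L))
  g <- mor_geometry(NULL, c(72L, 94L), 124L)
  expect_null(g$mor5p_window)
  expect_null(g$loop)
  expect_equal(g$mor3p_window, c(91L, 124L))
})
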