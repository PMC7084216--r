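test_that("make_hairpin plants analytically consistent truth", {
  hp <- make_hairpin(seed = 61L, mature_arm = "3p", name = "sim-mir-9")
  tr <- hp$truth
  expect_setequal(tr$name, c("miR-9-5p", "miR-9-3p", "moR-9-5p", "moR-9-3p",
                             "loop-9"))
  # the fold-projected star equals the planted 5p product
  star <- project_star(c(tr$start[tr$name == "miR-9-3p"],
                         tr$end[tr$name == "miR-9-3p"]), hp$fold)
  expect_equal(star, c(tr$start[tr$name == "miR-9-5p"],
                       tr$end[tr$name == "miR-9-5p"]))
  # truth sequences come from the extended sequence
  for (i in seq_len(nrow(tr))) {
    expect_equal(tr$seq[i], substr(hp$ext_seq, tr$start[i] + 1, tr$end[i]))
  }
  # determinism: same seed, byte-identical construct
  hp2 <- make_hairpin(seed = 61L, mature_arm = "3p", name = "sim-mir-9")
  expect_identical(hp$ext_seq, hp2$ext_seq)
  expect_identical(hp$truth, hp2$truth)
})

test_that("bulged hairpins still fold into a dominant stem", {
  hp <- make_hairpin(seed = 62L, bulges = 1L, name = "sim-mir-8")
  o5 <- hp$flank
  arm5 <- (o5 + 1L):(o5 + hp$stem_len)
  expect_gte(mean(!is.na(hp$fold$pairs[arm5])), 0.9)
})

test_that("make_genome embeds recoverable annotation on both strands", {
  set.seed(63)
  hairpins <- lapply(1:3, function(i)
    make_hairpin(mature_arm = "3p", name = paste0("sim-mir-", i)))
  sim <- make_genome(hairpins, strands = c("+", "-", "+"))
  g <- sim$genome[[1]]
  for (i in 1:3) {
    p <- sim$precursors[i, ]
    slice <- as.character(Biostrings::subseq(g, p$start + 1L, p$end))
    if (p$strand == "-") slice <- revcomp(slice)
    hp <- hairpins[[i]]
    expected <- substr(hp$ext_seq, hp$prec_local[1] + 1, hp$prec_local[2])
    expect_equal(slice, expected)
  }
  # planted truth sequences are recoverable from the genome too
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    slice <- as.character(Biostrings::subseq(g, tr$gstart + 1L, tr$gend))
    if (tr$strand == "-") slice <- revcomp(slice)
    expect_equal(slice, tr$seq)
  }
})

test_that("repeat_spec plants a tag at exactly k intergenic loci", {
  set.seed(64)
  hairpins <- list(make_hairpin(name = "sim-mir-1"))
  sim <- make_genome(hairpins, repeat_spec = list(k = 6L))
  hits <- oracle_genome_hits(sim$repeat_tag$seq,
                             stats::setNames(as.character(sim$genome),
                                             names(sim$genome)))
  expect_equal(sum(hits$strand == "+"), 6L)
  # none overlaps the precursor
  p <- sim$precursors
  expect_false(any(hits$start < p$end & hits$end > p$start &
                     hits$strand == p$strand))
})

test_that("simulate_reads builds the requested isoform mixture", {
  set.seed(65)
  sim <- make_genome(list(make_hairpin(name = "sim-mir-1")))
  rd <- simulate_reads(sim, counts = c(mir = 40L, new_mir = 20L, mor = 0L,
                                       loop = 0L),
                       isoform_mix = c(canonical = 0.8, mm2_3p = 0.1,
                                       short3p = 0.1),
                       adapter = NULL)
  expect_equal(nrow(rd$reads), 60L)
  tab <- table(rd$manifest$isoform_type)
  expect_equal(unname(tab[c("canonical", "mm2_3p", "short3p")]),
               c(48L, 6L, 6L), ignore_attr = TRUE)
  # mm2_3p reads align to the precursor with 2 mm at the 3'-terminal
  # positions of the read
  ext <- sim$exts[[1]]
  m2 <- rd$reads$seq[rd$manifest$isoform_type == "mm2_3p"][1]
  aln <- align_to_precursor(m2, ext)
  expect_equal(aln$mm, 2L)
  l <- nchar(m2)
  expect_equal(aln$mm_pos, paste(l - 2L, l - 1L, sep = ","))
  expect_true(all(filter_two_mismatch_3prime(aln)))
})

test_that("planted low-quality reads fail the quality filter", {
  set.seed(66)
  sim <- make_genome(list(make_hairpin(name = "sim-mir-1")))
  rd <- simulate_reads(sim, counts = c(mir = 5L, new_mir = 0L, mor = 0L,
                                       loop = 0L),
                       adapter = NULL,
                       qual_model = list(phred = 40L,
                                         lowq = list(srna = "miR-1-3p",
                                                     n_reads = 3L)))
  qf <- quality_filter(rd$reads, preprocess_params())
  expect_equal(sum(!qf$pass), 3L)
  expect_true(all(qf$reason[!qf$pass] == "max_lowq_bases"))
})

test_that("simulate_dataset is byte-deterministic in its seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(d1, seed = 99L, n_precursors = 2L)
  s2 <- simulate_dataset(d2, seed = 99L, n_precursors = 2L)
  for (f in c("genome.fa", "annotation.gff3", "sample_1.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  s3 <- simulate_dataset(withr::local_tempdir(), seed = 100L,
                         n_precursors = 2L)
  expect_false(identical(readLines(s1$paths[["fastq"]]),
                         readLines(s3$paths[["fastq"]])))
})
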