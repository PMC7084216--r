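# Deterministic, seeded generator of synthetic genomes, hairpin precursors,
# annotations and FASTQ reads with planted miR/star/moR/loop truth.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a hairpin precursor with analytically known product truth
#'
#' Builds a perfect-stem hairpin (5' arm + loop + reverse-complement 3' arm)
#' with random flanks, places the annotated mature on the requested arm, and
#' computes the star, moR-5p, moR-3p and loop truth intervals analytically
#' from the duplex geometry (2-nt 3' overhang). The construct is
#' rejection-sampled (deterministically from the current RNG state) until the
#' built-in folder's star projection of the mature reproduces the analytic
#' star exactly, so the planted truth is guaranteed to be what the pipeline's
#' structure-based projection recovers. With `bulges > 0` single bases are
#' inserted into the 3' arm; the construct is then only required to pair at
#' least 90% of the 5' arm, and the star truth is taken from the fold.
#'
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param stem_len Stem length in bp (default 30; must be >= `mir_len`).
#' @param loop_len Terminal loop length in nt (default 14, >= 4).
#' @param mir_len Mature miRNA length in nt (default 22, >= 16).
#' @param bulges Number of single-base bulges inserted into the 3' arm.
#' @param mature_arm `"5p"`, `"3p"` or `"both"`: which arm(s) carry an
#'   annotated mature (the other arm's product is the predicted star).
#' @param flank Flank length in nt (default 30).
#' @param mor_len,mor_overlap moRNA truth length and its overlap with the
#'   adjacent miR in nt (defaults 20 and 2, the few-terminal-bases overlap of
#'   real moRs).
#' @param name Precursor name (miRBase style, e.g. `"sim-mir-7"`).
#' @param max_tries Rejection-sampling budget.
#' @return A `sim_hairpin` list: `name`, `id`, `ext_seq` (flank5 + precursor
#'   + flank3), `flank`, `prec_local`, `matures` (annotated, local), and
#'   `truth` (data.frame of all planted products with local intervals and
#'   sequences).
#' @export
make_hairpin <- function(seed = NULL, stem_len = 30L, loop_len = 14L,
                         mir_len = 22L, bulges = 0L, mature_arm = "3p",
                         flank = 30L, mor_len = 20L, mor_overlap = 2L,
                         name = "sim-mir-1", max_tries = 50L) {
  stopifnot(stem_len >= mir_len, mir_len >= 16L, loop_len >= 4L)
  if (!is.null(seed)) set.seed(seed)
  inset <- min(4L, stem_len - mir_len)
  o5 <- flank
  o3 <- flank + stem_len + loop_len
  plen <- 2L * stem_len + loop_len
  # analytic perfect-pairing partner of local position x (0-based)
  p0 <- function(x) {
    ifelse(x < o5 + stem_len,
           o3 + (stem_len - 1L) - (x - o5),
           o5 + (stem_len - 1L) - (x - o3))
  }
  star_of <- function(iv) {
    c(p0(iv[2L] - 1L) + 2L, p0(iv[1L]) + 3L)
  }
  mir3p <- c(o3 + inset, o3 + inset + mir_len)
  mir5p <- star_of(mir3p)
  for (try in seq_len(max_tries)) {
    arm5 <- rand_dna(stem_len)
    loop <- rand_dna(loop_len)
    arm3 <- revcomp(arm5)
    if (bulges > 0L) {
      pos <- sort(sample(seq_len(nchar(arm3) - 1L), bulges))
      for (b in rev(pos)) {
        arm3 <- paste0(substr(arm3, 1L, b), rand_dna(1L),
                       substr(arm3, b + 1L, nchar(arm3)))
      }
    }
    ext_seq <- paste0(rand_dna(flank), arm5, loop, arm3, rand_dna(flank))
    f <- fold_hairpin(ext_seq)
    if (bulges > 0L) {
      arm5_paired <- mean(!is.na(f$pairs[(o5 + 1L):(o5 + stem_len)]))
      if (arm5_paired < 0.9) next
      star <- project_star(mir3p, f)
      if (is.null(star)) next
      mir5p_use <- star
    } else {
      star <- project_star(mir3p, f)
      if (is.null(star) || !identical(as.integer(star), as.integer(mir5p))) next
      mir5p_use <- mir5p
    }
    ext_len <- nchar(ext_seq)
    mor5p <- c(mir5p_use[1L] - (mor_len - mor_overlap),
               mir5p_use[1L] + mor_overlap)
    mor3p <- c(mir3p[2L] - mor_overlap,
               mir3p[2L] + (mor_len - mor_overlap))
    loop_iv <- c(mir5p_use[2L], mir3p[1L])
    if (mor5p[1L] < 0L || mor3p[2L] > ext_len) next
    cls5 <- if (mature_arm %in% c("5p", "both")) "mir" else "new_mir"
    cls3 <- if (mature_arm %in% c("3p", "both")) "mir" else "new_mir"
    truth <- data.frame(
      precursor_id = name, precursor_name = name,
      class = c(cls5, cls3, "mor", "mor", "loop"),
      arm = c("5p", "3p", "5p", "3p", "loop"),
      start = c(mir5p_use[1L], mir3p[1L], mor5p[1L], mor3p[1L], loop_iv[1L]),
      end = c(mir5p_use[2L], mir3p[2L], mor5p[2L], mor3p[2L], loop_iv[2L]),
      stringsAsFactors = FALSE)
    truth$name <- mapply(name_srna, name, truth$class, truth$arm,
                         USE.NAMES = FALSE)
    truth$seq <- substring(ext_seq, truth$start + 1L, truth$end)
    annotated <- c(if (mature_arm %in% c("5p", "both")) 1L,
                   if (mature_arm %in% c("3p", "both")) 2L)
    matures <- truth[annotated, c("name", "start", "end"), drop = FALSE]
    matures$id <- paste0(name, "_mat_", matures$name)
    return(structure(list(name = name, id = name, ext_seq = ext_seq,
                          flank = flank, prec_local = c(o5, o5 + plen),
                          stem_len = stem_len, loop_len = loop_len,
                          matures = matures, truth = truth, fold = f),
                     class = "sim_hairpin"))
  }
  stop("make_hairpin: no admissible hairpin in ", max_tries, " tries")
}

#' Embed simulated hairpins in a synthetic genome with annotation
#'
#' Precursors (their extended sequences, so the planted flank truth is
#' genomic) are embedded at non-overlapping loci separated by random
#' background, on the requested strands. Optionally plants a repeat tag at
#' `k` intergenic loci (to exercise the multi-mapping rule) and `n_decoys`
#' unannotated random decoy sequences.
#'
#' @param hairpins List of [make_hairpin()] objects.
#' @param n_decoys Number of unannotated random 60-nt decoy insertions.
#' @param repeat_spec Optional list `list(seq =, k =)`: plant `seq` at `k`
#'   intergenic loci (`seq` defaults to a random 22-mer if `TRUE`).
#' @param seed Optional integer seed.
#' @param chrom Chromosome name.
#' @param strands Strand per hairpin, recycled (default alternating `+`/`-`).
#' @param gap_range Range of intergenic gap lengths.
#' @return A `sim_genome` list: `genome` ([Biostrings::DNAStringSet]),
#'   `precursors`, `matures` (annotation data.frames, 0-based internal),
#'   `exts` (anchored `extended_precursor`-compatible records), `truth`
#'   (all planted products with local and genomic coordinates) and
#'   `repeat_tag`.
#' @export
make_genome <- function(hairpins, n_decoys = 0L, repeat_spec = NULL,
                        seed = NULL, chrom = "chrSim",
                        strands = c("+", "-"), gap_range = c(200L, 600L)) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(hairpins)
  strands <- rep_len(strands, n)
  pieces <- character(0)
  pos <- 0L
  exts <- vector("list", n)
  gaps <- list()
  add_gap <- function() {
    g <- sample(gap_range[1L]:gap_range[2L], 1L)
    pieces <<- c(pieces, rand_dna(g))
    gaps[[length(gaps) + 1L]] <<- c(pos, pos + g)
    pos <<- pos + g
  }
  for (i in seq_len(n)) {
    add_gap()
    hp <- hairpins[[i]]
    ins <- if (strands[i] == "+") hp$ext_seq else revcomp(hp$ext_seq)
    ext <- list(id = hp$id, name = hp$name, seq = hp$ext_seq, chrom = chrom,
                strand = strands[i], gstart_ext = pos,
                flank5 = hp$flank, flank3 = hp$flank,
                prec_local = hp$prec_local)
    class(ext) <- "extended_precursor"
    exts[[i]] <- ext
    pieces <- c(pieces, ins)
    pos <- pos + nchar(ins)
  }
  add_gap()
  # decoys and repeats live in fresh intergenic gaps
  decoy_seqs <- character(0)
  for (d in seq_len(n_decoys)) {
    decoy_seqs <- c(decoy_seqs, rand_dna(60L))
    pieces <- c(pieces, decoy_seqs[d])
    pos <- pos + 60L
    add_gap()
  }
  repeat_tag <- NULL
  if (!is.null(repeat_spec)) {
    tag <- repeat_spec$seq
    if (is.null(tag)) tag <- rand_dna(22L)
    for (k in seq_len(repeat_spec$k)) {
      pieces <- c(pieces, tag)
      pos <- pos + nchar(tag)
      add_gap()
    }
    repeat_tag <- list(seq = tag, k = repeat_spec$k)
  }
  genome <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(genome) <- chrom

  precursors <- do.call(rbind, lapply(exts, function(e) {
    g <- local_to_genomic(e, e$prec_local[1L], e$prec_local[2L])
    data.frame(id = e$id, name = e$name, chrom = chrom,
               start = g[1L], end = g[2L], strand = e$strand,
               stringsAsFactors = FALSE)
  }))
  matures <- do.call(rbind, lapply(seq_len(n), function(i) {
    hp <- hairpins[[i]]; e <- exts[[i]]
    do.call(rbind, lapply(seq_len(nrow(hp$matures)), function(j) {
      g <- local_to_genomic(e, hp$matures$start[j], hp$matures$end[j])
      data.frame(id = hp$matures$id[j], name = hp$matures$name[j],
                 chrom = chrom, start = g[1L], end = g[2L],
                 strand = e$strand, precursor_id = hp$id,
                 stringsAsFactors = FALSE)
    }))
  }))
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- hairpins[[i]]$truth
    e <- exts[[i]]
    g <- t(vapply(seq_len(nrow(tr)), function(j)
      local_to_genomic(e, tr$start[j], tr$end[j]), integer(2)))
    tr$chrom <- chrom
    tr$gstart <- g[, 1L]
    tr$gend <- g[, 2L]
    tr$strand <- e$strand
    tr
  }))
  structure(list(genome = genome, precursors = precursors, matures = matures,
                 exts = exts, hairpins = hairpins, truth = truth,
                 repeat_tag = repeat_tag, decoys = decoy_seqs),
            class = "sim_genome")
}

#' Write a simulated annotation as miRBase-dialect GFF3
#' @param sim A [make_genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  p <- sim$precursors
  writeLines(paste(p$chrom, "moRquant_sim", "miRNA_primary_transcript",
                   p$start + 1L, p$end, ".", p$strand, ".",
                   paste0("ID=", p$id, ";Name=", p$name), sep = "\t"), con)
  m <- sim$matures
  if (!is.null(m) && nrow(m)) {
    writeLines(paste(m$chrom, "moRquant_sim", "miRNA",
                     m$start + 1L, m$end, ".", m$strand, ".",
                     paste0("ID=", m$id, ";Name=", m$name,
                            ";Derives_from=", m$precursor_id), sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate small RNA-seq reads from planted truth
#'
#' Each planted sRNA emits `counts[class]` reads (overridable per sRNA name),
#' split across isoform types by `isoform_mix` (deterministic allocation,
#' remainder to canonical). Variant reads are built from the extended
#' precursor template: end offsets use templated bases, `mm1` substitutes an
#' internal base, `mm2_3p` appends two non-templated 3' bases. The 3' adapter
#' is appended (unless `NULL`) and Phred qualities come from `qual_model`.
#' Errors are planted, not stochastic.
#'
#' @param sim A [make_genome()] object.
#' @param counts Named integer vector of read counts per class
#'   (`mir`, `new_mir`, `mor`, `loop`, optionally `decoy`).
#' @param isoform_mix Named numeric fractions over isoform types summing to
#'   <= 1 (default pure canonical).
#' @param adapter 3' adapter appended to every read, or `NULL`.
#' @param qual_model List: `phred` (default base quality, 40), `per_srna`
#'   (named numeric, per-sRNA flat quality override), `lowq` (optional
#'   `list(srna =, n_reads =, n_bases = 3, phred = 10)`: plants `n_reads`
#'   extra reads of that sRNA with `n_bases` low-quality bases).
#' @param seed Optional integer seed (shuffling of read order).
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `manifest`
#'   (truth label per read).
#' @export
simulate_reads <- function(sim,
                           counts = c(mir = 500L, new_mir = 120L,
                                      mor = 50L, loop = 25L),
                           isoform_mix = c(canonical = 1),
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           qual_model = list(phred = 40L),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(isoform_mix) %in% isoform_types))
  phred_default <- if (is.null(qual_model$phred)) 40L else qual_model$phred
  overrides <- qual_model$per_srna
  count_overrides <- qual_model$count_overrides
  exts_by_id <- stats::setNames(sim$exts, vapply(sim$exts, `[[`, "", "id"))

  variant_read <- function(type, iv, ext_seq) {
    s <- iv[1L]; e <- iv[2L]
    sub_at <- function(seq, pos) { # pos 1-based; cycle to a different base
      b <- substr(seq, pos, pos)
      repl <- c(A = "C", C = "G", G = "T", T = "A")[[b]]
      paste0(substr(seq, 1L, pos - 1L), repl,
             substr(seq, pos + 1L, nchar(seq)))
    }
    switch(type,
      canonical = substr(ext_seq, s + 1L, e),
      mm1 = sub_at(substr(ext_seq, s + 1L, e), max(2L, (e - s) %/% 2L)),
      mm2_3p = {
        base <- substr(ext_seq, s + 1L, e)
        tmpl <- strsplit(substr(ext_seq, e + 1L, e + 2L), "")[[1L]]
        added <- vapply(tmpl, function(b)
          c(A = "C", C = "G", G = "T", T = "A")[[b]], character(1))
        paste0(base, paste(added, collapse = ""))
      },
      short5p = substr(ext_seq, s + 2L, e),
      short3p = substr(ext_seq, s + 1L, e - 1L),
      long5p = substr(ext_seq, s, e),
      long3p = substr(ext_seq, s + 1L, e + 1L),
      len_both = substr(ext_seq, s + 2L, e - 1L))
  }

  seqs <- character(0); labels <- character(0); types <- character(0)
  quals <- character(0)
  emit <- function(seq, n, label, type, phred, lowq = NULL) {
    if (n <= 0L) return()
    read <- if (is.null(adapter)) seq else paste0(seq, adapter)
    q <- strrep(intToUtf8(phred + 33L), nchar(read))
    if (!is.null(lowq)) {
      insert_len <- nchar(seq)
      qv <- rep(phred, nchar(read))
      qv[seq_len(min(lowq$n_bases, insert_len))] <- lowq$phred
      q <- intToUtf8(qv + 33L)
    }
    seqs <<- c(seqs, rep(read, n))
    quals <<- c(quals, rep(q, n))
    labels <<- c(labels, rep(label, n))
    types <<- c(types, rep(type, n))
  }

  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ext_seq <- exts_by_id[[tr$precursor_id]]$seq
    n <- if (!is.null(count_overrides) && tr$name %in% names(count_overrides))
      count_overrides[[tr$name]]
    else if (tr$class %in% names(counts)) counts[[tr$class]] else 0L
    if (is.null(n) || n <= 0L) next
    phred <- if (!is.null(overrides) && tr$name %in% names(overrides))
      overrides[[tr$name]] else phred_default
    alloc <- floor(isoform_mix * n)
    alloc["canonical"] <- n - sum(alloc[names(alloc) != "canonical"])
    for (type in names(alloc)) {
      emit(variant_read(type, c(tr$start, tr$end), ext_seq),
           alloc[[type]], tr$name, type, phred)
    }
  }
  if (!is.null(sim$repeat_tag) && "decoy" %in% names(counts)) {
    emit(sim$repeat_tag$seq, counts[["decoy"]], "decoy", "canonical",
         phred_default)
  }
  if (!is.null(qual_model$lowq)) {
    lw <- qual_model$lowq
    tr <- sim$truth[sim$truth$name == lw$srna, ][1L, ]
    ext_seq <- exts_by_id[[tr$precursor_id]]$seq
    emit(variant_read("canonical", c(tr$start, tr$end), ext_seq),
         lw$n_reads, lw$srna, "lowq", phred_default,
         lowq = list(n_bases = if (is.null(lw$n_bases)) 3L else lw$n_bases,
                     phred = if (is.null(lw$phred)) 10L else lw$phred))
  }
  ord <- sample.int(length(seqs))
  reads <- data.frame(id = sprintf("r%06d", seq_along(seqs)),
                      seq = seqs[ord], qual = quals[ord],
                      stringsAsFactors = FALSE)
  manifest <- data.frame(id = reads$id, srna = labels[ord],
                         isoform_type = types[ord], stringsAsFactors = FALSE)
  list(reads = reads, manifest = manifest)
}

#' One-call simulated dataset on disk
#'
#' Builds `n_precursors` hairpins (annotated arms cycling through 3p, 5p,
#' both; strands alternating), embeds them in a genome, simulates one sample
#' of reads and writes `genome.fa`, `annotation.gff3`, `sample_1.fastq` and
#' `truth.tsv` under `outdir`. Fully determined by `seed`.
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving all randomness.
#' @param n_precursors Number of hairpin precursors (default 5).
#' @param counts,isoform_mix,adapter,qual_model Passed to [simulate_reads()].
#' @param repeat_spec,n_decoys Passed to [make_genome()].
#' @return List with `paths`, `sim`, `manifest` and `truth` (the expected
#'   sRNA table including planted read counts).
#' @export
simulate_dataset <- function(outdir, seed, n_precursors = 5L,
                             counts = c(mir = 500L, new_mir = 120L,
                                        mor = 50L, loop = 25L),
                             isoform_mix = c(canonical = 1),
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             qual_model = list(phred = 40L),
                             repeat_spec = NULL, n_decoys = 0L) {
  set.seed(seed)
  arms <- rep_len(c("3p", "5p", "both"), n_precursors)
  hairpins <- lapply(seq_len(n_precursors), function(i)
    make_hairpin(mature_arm = arms[i], name = paste0("sim-mir-", i)))
  sim <- make_genome(hairpins, repeat_spec = repeat_spec, n_decoys = n_decoys)
  rd <- simulate_reads(sim, counts = counts, isoform_mix = isoform_mix,
                       adapter = adapter, qual_model = qual_model)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             annotation = file.path(outdir, "annotation.gff3"),
             fastq = file.path(outdir, "sample_1.fastq"),
             truth = file.path(outdir, "truth.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write_annotation_gff3(sim, paths[["annotation"]])
  write_fastq(rd$reads, paths[["fastq"]])
  truth <- sim$truth
  nm <- if (!is.null(qual_model$count_overrides)) qual_model$count_overrides else list()
  truth$planted_count <- vapply(seq_len(nrow(truth)), function(i) {
    if (truth$name[i] %in% names(nm)) as.integer(nm[[truth$name[i]]])
    else if (truth$class[i] %in% names(counts))
      as.integer(counts[[truth$class[i]]])
    else 0L
  }, integer(1))
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(paths = paths, sim = sim, manifest = rd$manifest, truth = truth)
}
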