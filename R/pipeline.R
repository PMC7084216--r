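# Pipeline orchestration, configuration and the command-line entry point.

#' Build a run configuration
#'
#' Parameter keys mirror the published spellings (`MIN_COUNT`,
#' `MAX_LEN_FILTER`, `MEAN_QUAL_FILTER`, `MIN_MORNA_LEN`, `MORFILTER`,
#' `ALLOWED_OVERHANG`, `NOADAPTER`, `ADAPTER`), so published settings
#' transcribe verbatim.
#'
#' @param samples Named character vector: sample name -> FASTQ path.
#' @param genome Path to the reference genome FASTA.
#' @param annotation Path to the miRBase-dialect GFF3 annotation.
#' @param extra_precursors Optional path to an extra (predicted) precursor
#'   GFF3 in the same dialect.
#' @param fold_tsv Optional path to per-precursor external dot-bracket TSV
#'   (external-fold mode).
#' @param outdir Output directory.
#' @param ADAPTER 3' adapter sequence, or `NULL`.
#' @param NOADAPTER Disable adapter trimming (reads already trimmed).
#' @param MIN_LEN,MAX_LEN_FILTER Length bounds after trimming (18/30).
#' @param MEAN_QUAL_FILTER Minimum mean Phred (30).
#' @param MIN_COUNT Minimum collapsed tag count (10).
#' @param MAX_OUTSIDE_LOCI Multi-mapping tolerance (5).
#' @param ALLOWED_OVERHANG Assignment end tolerance in nt (3).
#' @param MIN_MORNA_LEN Minimum moRNA length (16).
#' @param MORFILTER `"conservative"` or `"permissive"`.
#' @param flank Precursor flank length in nt (30).
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(samples, genome, annotation, extra_precursors = NULL,
                       fold_tsv = NULL, outdir = "morquant_out",
                       ADAPTER = NULL, NOADAPTER = is.null(ADAPTER),
                       MIN_LEN = 18L, MAX_LEN_FILTER = 30L,
                       MEAN_QUAL_FILTER = 30, MIN_COUNT = 10L,
                       MAX_OUTSIDE_LOCI = 5L, ALLOWED_OVERHANG = 3L,
                       MIN_MORNA_LEN = 16L,
                       MORFILTER = "conservative", flank = 30L, seed = 1L) {
  structure(list(samples = samples, genome = genome, annotation = annotation,
                 extra_precursors = extra_precursors, fold_tsv = fold_tsv,
                 outdir = outdir, ADAPTER = ADAPTER, NOADAPTER = NOADAPTER,
                 MIN_LEN = as.integer(MIN_LEN),
                 MAX_LEN_FILTER = as.integer(MAX_LEN_FILTER),
                 MEAN_QUAL_FILTER = MEAN_QUAL_FILTER,
                 MIN_COUNT = as.integer(MIN_COUNT),
                 MAX_OUTSIDE_LOCI = as.integer(MAX_OUTSIDE_LOCI),
                 ALLOWED_OVERHANG = as.integer(ALLOWED_OVERHANG),
                 MIN_MORNA_LEN = as.integer(MIN_MORNA_LEN),
                 MORFILTER = MORFILTER, flank = as.integer(flank),
                 seed = seed),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Checks file existence, parameter ranges, the adapter alphabet, and that
#' `NOADAPTER` and `ADAPTER` are mutually exclusive. Violations are returned,
#' not thrown.
#'
#' @param config A [run_config()] object.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  for (s in names(config$samples)) {
    if (!file.exists(config$samples[[s]]))
      note(paste0("sample '", s, "': FASTQ not found: ", config$samples[[s]]))
  }
  if (!length(config$samples)) note("no samples configured")
  if (is.null(config$genome) || !file.exists(config$genome))
    note("genome not found")
  if (is.null(config$annotation) || !file.exists(config$annotation))
    note("annotation not found")
  if (!is.null(config$extra_precursors) && !file.exists(config$extra_precursors))
    note("extra precursor GFF3 not found")
  if (isTRUE(config$NOADAPTER) && !is.null(config$ADAPTER))
    note("NOADAPTER=TRUE and ADAPTER are mutually exclusive")
  if (!isTRUE(config$NOADAPTER)) {
    if (is.null(config$ADAPTER) || !nzchar(config$ADAPTER))
      note("ADAPTER must be set unless NOADAPTER=TRUE")
    else if (grepl("[^ACGT]", toupper(config$ADAPTER)))
      note("ADAPTER contains non-ACGT characters")
  }
  if (config$MIN_LEN < 1L || config$MIN_LEN > config$MAX_LEN_FILTER)
    note("MIN_LEN must satisfy 1 <= MIN_LEN <= MAX_LEN_FILTER")
  if (config$MIN_COUNT < 1L) note("MIN_COUNT must be >= 1")
  if (config$ALLOWED_OVERHANG < 0L) note("ALLOWED_OVERHANG must be >= 0")
  if (config$MIN_MORNA_LEN < 1L) note("MIN_MORNA_LEN must be >= 1")
  if (config$MAX_OUTSIDE_LOCI < 0L) note("MAX_OUTSIDE_LOCI must be >= 0")
  if (!config$MORFILTER %in% c("conservative", "permissive"))
    note("MORFILTER must be 'conservative' or 'permissive'")
  v
}

#' Read a flat key=value configuration file with a [samples] section
#' @param path Path to the config file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  in_samples <- FALSE
  kv <- list()
  samples <- character(0)
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      in_samples <- identical(tolower(ln), "[samples]")
      next
    }
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    if (in_samples) samples[key] <- val else kv[[key]] <- val
  }
  num_keys <- c("MIN_LEN", "MAX_LEN_FILTER", "MEAN_QUAL_FILTER", "MIN_COUNT",
                "MAX_OUTSIDE_LOCI", "ALLOWED_OVERHANG", "MIN_MORNA_LEN",
                "flank", "seed")
  args <- list(samples = samples)
  for (k in names(kv)) {
    val <- kv[[k]]
    if (k %in% num_keys) val <- as.numeric(val)
    if (k == "NOADAPTER") val <- toupper(val) %in% c("TRUE", "T", "1", "YES")
    args[[k]] <- val
  }
  do.call(run_config, args)
}

#' Run the full pipeline
#'
#' Per sample: preprocessing (trim, quality filter, collapse, low-count
#' filter) -> exact genome matching with the multi-mapping rule -> alignment
#' to extended precursors (<= 2 mismatches, 2-mm restricted to 3' ends) ->
#' alignment blocks -> sRNA finalization (expressed miRs, star-projected new
#' miRs, moRs, loop) -> moR sequence filter -> read assignment and isoform
#' classification. Samples are independent; the run is deterministic for a
#' fixed configuration.
#'
#' @param config A [run_config()] object.
#' @param write Write output files under `config$outdir` (default TRUE).
#' @return A `morna_results` object: `catalog` (genomic sRNA catalog),
#'   `counts` (sRNA x sample matrix), `row_meta`, `isoforms`, `unassigned`,
#'   `stats` (per-sample stage counts) and `defs` (per-sample definitions).
#' @export
run_pipeline <- function(config, write = TRUE) {
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  log_lines <- c(paste0("# moRquant run, seed=", config$seed),
                 paste0("# params: ", paste(
                   vapply(c("MIN_LEN", "MAX_LEN_FILTER", "MEAN_QUAL_FILTER",
                            "MIN_COUNT", "MAX_OUTSIDE_LOCI", "ALLOWED_OVERHANG",
                            "MIN_MORNA_LEN", "MORFILTER"),
                          function(k) paste0(k, "=", config[[k]]), character(1)),
                   collapse = " ")))
  genome <- read_genome(config$genome)
  ann <- read_mir_gff3(config$annotation)
  precursors <- ann$precursors
  if (!is.null(config$extra_precursors)) {
    extra <- read_mir_gff3(config$extra_precursors)
    precursors <- rbind(precursors, extra$precursors)
    ann$matures <- rbind(ann$matures, extra$matures)
  }
  index <- build_genome_index(genome, precursors)
  mm_params <- multimap_params(max_outside_loci = config$MAX_OUTSIDE_LOCI)
  pp_params <- preprocess_params(
    adapter = config$ADAPTER, min_len = config$MIN_LEN,
    max_len = config$MAX_LEN_FILTER, mean_qual = config$MEAN_QUAL_FILTER,
    min_count = config$MIN_COUNT, noadapter = config$NOADAPTER)
  as_params <- assign_params(allowed_overhang = config$ALLOWED_OVERHANG,
                             min_morna_len = config$MIN_MORNA_LEN,
                             morfilter = config$MORFILTER)
  ext_structures <- if (!is.null(config$fold_tsv))
    read_fold_tsv(config$fold_tsv) else NULL

  exts <- lapply(seq_len(nrow(precursors)), function(i) {
    prec <- precursors[i, ]
    mt <- ann$matures[ann$matures$precursor_id == prec$id, , drop = FALSE]
    extend_precursor(prec, genome, mt, flank = config$flank)
  })
  folds <- lapply(exts, function(e) {
    st <- if (!is.null(ext_structures) && e$id %in% names(ext_structures))
      ext_structures[[e$id]] else NULL
    fold_hairpin(e$seq, structure = st)
  })

  all_iso <- list()
  all_unassigned <- list()
  all_defs <- list()
  stats <- list()
  for (sname in names(config$samples)) {
    reads <- read_fastq(config$samples[[sname]])
    pp <- preprocess_reads(reads, pp_params)
    gf <- filter_tags_genome(pp$tags, index, mm_params)
    tags <- gf$tags

    # align every tag to every extended precursor, best stratum,
    # 2-mm alignments restricted to 3'-terminal mismatches
    alns <- list()
    for (pi in seq_along(exts)) {
      ext <- exts[[pi]]
      for (ti in seq_len(nrow(tags))) {
        a <- align_to_precursor(tags$seq[ti], ext)
        if (!nrow(a)) next
        a <- a[filter_two_mismatch_3prime(a), , drop = FALSE]
        if (!nrow(a)) next
        a$seq <- tags$seq[ti]
        a$count <- tags$count[ti]
        a$precursor_id <- ext$id
        alns[[length(alns) + 1L]] <- a
      }
    }
    alns <- if (length(alns)) do.call(rbind, alns) else
      data.frame(start = integer(0), end = integer(0), mm = integer(0),
                 mm_pos = character(0), seq = character(0), count = integer(0),
                 precursor_id = character(0), stringsAsFactors = FALSE)

    # blocks from perfect alignments; sRNA definitions per precursor
    defs <- do.call(rbind, lapply(seq_along(exts), function(pi) {
      ext <- exts[[pi]]
      sub <- alns[alns$precursor_id == ext$id & alns$mm == 0L, , drop = FALSE]
      blocks <- build_blocks(sub)
      finalize_srnas(ext, folds[[pi]], blocks, as_params)
    }))
    if (is.null(defs))
      defs <- data.frame(precursor_id = character(0),
                         precursor_name = character(0), class = character(0),
                         arm = character(0), start = integer(0),
                         end = integer(0), name = character(0),
                         seq = character(0), support_count = integer(0),
                         stringsAsFactors = FALSE)
    defs <- mor_sequence_filter(defs, as_params$morfilter)

    # assign: one assignment per (tag, precursor); cross-precursor
    # assignments each receive the full tag count, flagged
    iso_rows <- list()
    assigned_tag <- logical(nrow(tags))
    names(assigned_tag) <- tags$seq
    tag_prec <- paste(alns$seq, alns$precursor_id)
    n_aln_assigned <- 0L
    for (tp in unique(tag_prec)) {
      rows <- which(tag_prec == tp)
      prec_id <- alns$precursor_id[rows[1L]]
      pdefs <- defs[defs$precursor_id == prec_id, , drop = FALSE]
      best <- NULL
      for (r in rows) {
        di <- assign_alignment(c(alns$start[r], alns$end[r]), pdefs, as_params)
        if (!is.na(di)) { best <- list(r = r, di = di); break }
      }
      if (is.null(best)) next
      r <- best$r
      d <- pdefs[best$di, ]
      n_aln_assigned <- n_aln_assigned + 1L
      assigned_tag[alns$seq[r]] <- TRUE
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        sample = sname, precursor_id = prec_id, srna = d$name,
        class = d$class,
        isoform_type = classify_isoform(c(alns$start[r], alns$end[r]),
                                        c(d$start, d$end), alns$mm[r]),
        offset5 = alns$start[r] - d$start, offset3 = alns$end[r] - d$end,
        mm_pos = alns$mm_pos[r], seq = alns$seq[r],
        count = alns$count[r], cross_map = NA, stringsAsFactors = FALSE)
    }
    iso <- if (length(iso_rows)) do.call(rbind, iso_rows) else
      data.frame(sample = character(0), precursor_id = character(0),
                 srna = character(0), class = character(0),
                 isoform_type = character(0), offset5 = integer(0),
                 offset3 = integer(0), mm_pos = character(0),
                 seq = character(0), count = integer(0),
                 cross_map = logical(0), stringsAsFactors = FALSE)
    if (nrow(iso)) {
      nprec <- table(iso$seq)
      iso$cross_map <- nprec[iso$seq] > 1L
    }
    unassigned <- tags[!assigned_tag, c("seq", "count"), drop = FALSE]
    if (nrow(unassigned)) unassigned$sample <- sname

    all_iso[[sname]] <- iso
    all_unassigned[[sname]] <- unassigned
    all_defs[[sname]] <- defs
    stats[[sname]] <- c(pp$stats, gf$stats,
                        list(n_tag_prec_pairs = length(unique(tag_prec)),
                             n_assigned_pairs = n_aln_assigned,
                             n_unassigned_tags = nrow(unassigned)))
    log_lines <- c(log_lines, sprintf(
      "sample=%s raw=%d no_adapter=%d empty_insert=%d qual_failed=%d N_dropped=%d tags=%d tags_kept=%d genome_kept=%d assigned_pairs=%d unassigned_tags=%d",
      sname, pp$stats$n_raw, pp$stats$n_no_adapter, pp$stats$n_empty_insert,
      pp$stats$n_qual_failed, pp$stats$n_dropped_N, pp$stats$n_tags,
      pp$stats$n_tags_kept, gf$stats$n_kept, n_aln_assigned, nrow(unassigned)))
  }

  iso_all <- do.call(rbind, all_iso)
  rownames(iso_all) <- NULL
  q <- quantify(iso_all)
  # genomic catalog: union of per-sample definitions
  defs_all <- unique(do.call(rbind, all_defs))
  catalog <- do.call(rbind, lapply(seq_len(nrow(defs_all)), function(i) {
    d <- defs_all[i, ]
    ext <- exts[[match(d$precursor_id, vapply(exts, `[[`, "", "id"))]]
    g <- local_to_genomic(ext, d$start, d$end)
    data.frame(chrom = ext$chrom, gstart = g[1L], gend = g[2L],
               strand = ext$strand, name = d$name, class = d$class,
               precursor_id = d$precursor_id, seq = d$seq,
               stringsAsFactors = FALSE)
  }))
  if (is.null(catalog)) {
    catalog <- data.frame(chrom = character(0), gstart = integer(0),
                          gend = integer(0), strand = character(0),
                          name = character(0), class = character(0),
                          precursor_id = character(0), seq = character(0),
                          stringsAsFactors = FALSE)
  } else {
    catalog <- unique(catalog)
    catalog <- catalog[order(catalog$chrom, catalog$gstart, catalog$name), ,
                       drop = FALSE]
    rownames(catalog) <- NULL
  }
  unassigned_all <- do.call(rbind, all_unassigned)
  if (is.null(unassigned_all))
    unassigned_all <- data.frame(seq = character(0), count = integer(0),
                                 sample = character(0), stringsAsFactors = FALSE)
  rownames(unassigned_all) <- NULL
  results <- structure(list(catalog = catalog, counts = q$counts,
                            row_meta = q$row_meta, isoforms = q$isoforms,
                            unassigned = unassigned_all, stats = stats,
                            defs = all_defs, config = config),
                       class = "morna_results")
  if (write) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_outputs(results, config$outdir)
    writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  }
  results
}

#' Command-line interface
#'
#' Subcommands: `run <config>`, `validate <config>`,
#' `simulate <outdir> <seed>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
morquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: morquant run <config> | validate <config> | simulate <outdir> <seed>"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  if (cmd == "validate") {
    v <- validate_config(read_run_config(args[2L]))
    if (length(v)) { message(paste(v, collapse = "\n")); return(invisible(1L)) }
    message("config OK")
  } else if (cmd == "run") {
    res <- run_pipeline(read_run_config(args[2L]))
    message("wrote outputs to ", res$config$outdir)
  } else if (cmd == "simulate") {
    simulate_dataset(args[2L], as.integer(args[3L]))
    message("wrote simulated dataset to ", args[2L])
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
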