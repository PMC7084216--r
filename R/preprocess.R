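# Adapter trimming, quality/length filtering, tag collapsing, low-count filter.

#' Preprocessing parameters
#'
#' Config-key spellings (`ADAPTER`, `NOADAPTER`, `MIN_LEN`, `MAX_LEN_FILTER`,
#' `MEAN_QUAL_FILTER`, `MIN_COUNT`) mirror the pipeline's published settings so
#' they transcribe directly.
#'
#' @param adapter 3' adapter DNA sequence, or `NULL` when reads are already
#'   trimmed (`NOADAPTER` mode).
#' @param min_len,max_len Post-trimming length bounds in nt (defaults 18/30).
#' @param mean_qual Minimum arithmetic mean Phred score (default 30).
#' @param max_lowq_bases Maximum number of bases below `lowq_phred` (fixed
#'   default 2 at Phred < 20).
#' @param lowq_phred Phred threshold defining a low-quality base (default 20).
#' @param min_count Minimum collapsed tag count; tags with count strictly
#'   below this are removed as background noise (default 10).
#' @param noadapter Logical; `TRUE` disables adapter trimming.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(adapter = NULL, min_len = 18L, max_len = 30L,
                              mean_qual = 30, max_lowq_bases = 2L,
                              lowq_phred = 20L, min_count = 10L,
                              noadapter = is.null(adapter)) {
  stopifnot(min_len >= 1L, min_len <= max_len, min_count >= 1L,
            max_lowq_bases >= 0L)
  if (!noadapter) {
    if (is.null(adapter) || !nzchar(adapter))
      stop("adapter must be non-empty unless noadapter = TRUE")
    if (grepl("[^ACGT]", toupper(adapter)))
      stop("adapter must be a DNA string over ACGT")
    adapter <- toupper(adapter)
  }
  structure(list(adapter = adapter, min_len = as.integer(min_len),
                 max_len = as.integer(max_len), mean_qual = mean_qual,
                 max_lowq_bases = as.integer(max_lowq_bases),
                 lowq_phred = as.integer(lowq_phred),
                 min_count = as.integer(min_count), noadapter = noadapter),
            class = "preprocess_params")
}

#' Trim the 3' adapter from reads
#'
#' Removes the best 3' occurrence of the adapter (partial adapter allowed at
#' the read end, error rate <= `max_error_rate`); the quality string is
#' trimmed in lockstep. Reads in which no adapter is found are discarded:
#' with read-through small RNA protocols an adapter-less read means the
#' insert was longer than the read. In `NOADAPTER` mode reads pass unchanged.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (see [read_fastq()]).
#' @param adapter Adapter DNA string, or `NULL` for NOADAPTER mode.
#' @param max_error_rate Maximum mismatch fraction in the matched portion.
#' @param min_overlap Minimum adapter overlap considered a match.
#' @return List with `reads` (trimmed, empty inserts and adapter-less reads
#'   removed), `n_no_adapter` and `n_empty_insert` counters.
#' @export
trim_adapter <- function(reads, adapter, max_error_rate = 0.1,
                         min_overlap = 3L) {
  if (is.null(adapter)) {
    return(list(reads = reads, n_no_adapter = 0L, n_empty_insert = 0L))
  }
  if (nrow(reads) == 0L) {
    return(list(reads = reads, n_no_adapter = 0L, n_empty_insert = 0L))
  }
  pos <- adapter_insert_len(reads$seq, toupper(adapter), max_error_rate,
                            as.integer(min_overlap))
  found <- pos >= 0L
  empty <- pos == 0L
  keep <- found & !empty
  out <- reads[keep, , drop = FALSE]
  if (nrow(out)) {
    out$seq <- substr(out$seq, 1L, pos[keep])
    out$qual <- substr(out$qual, 1L, pos[keep])
  }
  rownames(out) <- NULL
  list(reads = out, n_no_adapter = sum(!found), n_empty_insert = sum(empty))
}

phred_values <- function(qual) utf8ToInt(qual) - 33L

#' Length and quality filter for trimmed reads
#'
#' A read passes iff `min_len <= length <= max_len`, its arithmetic mean Phred
#' score is at least `mean_qual`, and it has at most `max_lowq_bases` bases
#' below Phred `lowq_phred`. The first violated criterion (in that order) is
#' reported as the failure reason.
#'
#' @param reads data.frame with `seq` and `qual`.
#' @param params A [preprocess_params()] object.
#' @return data.frame `reads` plus logical `pass` and character `reason`
#'   (`NA` for passing reads; one of `"min_len"`, `"max_len"`, `"mean_qual"`,
#'   `"max_lowq_bases"`).
#' @export
quality_filter <- function(reads, params) {
  n <- nrow(reads)
  len <- nchar(reads$seq)
  meanq <- numeric(n)
  nlow <- integer(n)
  for (i in seq_len(n)) {
    p <- phred_values(reads$qual[i])
    meanq[i] <- mean(p)
    nlow[i] <- sum(p < params$lowq_phred)
  }
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & len < params$min_len] <- "min_len"
  reason[is.na(reason) & len > params$max_len] <- "max_len"
  reason[is.na(reason) & meanq < params$mean_qual] <- "mean_qual"
  reason[is.na(reason) & nlow > params$max_lowq_bases] <- "max_lowq_bases"
  reads$pass <- is.na(reason)
  reads$reason <- reason
  reads
}

#' Collapse reads into counted unique sequence tags
#'
#' Reads containing `N` are dropped (exact matching is meaningless with `N`);
#' the number dropped is recorded in the `n_dropped_N` attribute. Tags are
#' returned ordered by decreasing count, ties by sequence.
#'
#' @param seqs Character vector of read sequences.
#' @return data.frame with `seq` and `count`; `sum(count)` equals
#'   `length(seqs)` minus the `N`-containing reads.
#' @export
collapse_tags <- function(seqs) {
  hasN <- grepl("N", seqs, fixed = TRUE)
  n_dropped <- sum(hasN)
  seqs <- seqs[!hasN]
  if (!length(seqs)) {
    out <- data.frame(seq = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(seqs)
    out <- data.frame(seq = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$seq), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped_N") <- n_dropped
  out
}

#' Remove low-count tags
#'
#' Tags with count strictly below `min_count` are treated as sequencing
#' background noise. `kept` and `dropped` partition the input; the operation
#' is idempotent and monotone in `min_count`.
#'
#' @param tags data.frame from [collapse_tags()].
#' @param min_count Minimum retained count (>= 1).
#' @return List with `kept` and `dropped` data.frames.
#' @export
filter_low_count <- function(tags, min_count) {
  stopifnot(min_count >= 1L)
  keep <- tags$count >= min_count
  list(kept = tags[keep, , drop = FALSE],
       dropped = tags[!keep, , drop = FALSE])
}

#' Full preprocessing stage: trim, filter, collapse, low-count filter
#'
#' @param reads data.frame from [read_fastq()].
#' @param params A [preprocess_params()] object.
#' @return List with `tags` (kept), `dropped_tags`, and `stats` (a named list
#'   of stage in/out counts satisfying the conservation identity:
#'   raw = no-adapter + empty-insert + quality-failed + N-dropped +
#'   sum of all tag counts).
#' @export
preprocess_reads <- function(reads, params) {
  n_raw <- nrow(reads)
  tr <- trim_adapter(reads, if (params$noadapter) NULL else params$adapter)
  qf <- quality_filter(tr$reads, params)
  passed <- qf[qf$pass, , drop = FALSE]
  tags <- collapse_tags(passed$seq)
  lc <- filter_low_count(tags, params$min_count)
  stats <- list(
    n_raw = n_raw,
    n_no_adapter = tr$n_no_adapter,
    n_empty_insert = tr$n_empty_insert,
    n_qual_failed = sum(!qf$pass),
    qual_fail_reasons = table(qf$reason[!qf$pass]),
    n_dropped_N = attr(tags, "n_dropped_N"),
    n_tag_reads = sum(tags$count),
    n_tags = nrow(tags),
    n_tags_kept = nrow(lc$kept),
    n_tag_reads_kept = sum(lc$kept$count)
  )
  list(tags = lc$kept, dropped_tags = lc$dropped, stats = stats)
}
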