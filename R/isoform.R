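# Isoform classification, counting and CPM normalization.

isoform_types <- c("canonical", "mm1", "mm2_3p", "short5p", "short3p",
                   "long5p", "long3p", "len_both")

#' Classify an assigned alignment into canonical or one of 7 isoform types
#'
#' Mismatch classes take precedence: one mismatch is `mm1`, two (already
#' filtered to 3'-terminal positions) are `mm2_3p`. Otherwise end deviations
#' relative to the canonical interval classify the read: 5'-only deviation is
#' `short5p`/`long5p` by sign, 3'-only `short3p`/`long3p`, both ends
#' `len_both`, none `canonical`. The full end offsets and mismatch positions
#' are retained in the isoform table so no information is lost by the single
#' label.
#'
#' @param aln Integer `c(start, end)` of the alignment (local coordinates).
#' @param canonical Integer `c(start, end)` of the assigned sRNA definition.
#' @param mm Number of mismatches (0-2).
#' @return One of `"canonical"`, `"mm1"`, `"mm2_3p"`, `"short5p"`,
#'   `"short3p"`, `"long5p"`, `"long3p"`, `"len_both"`.
#' @export
classify_isoform <- function(aln, canonical, mm = 0L) {
  if (mm == 1L) return("mm1")
  if (mm == 2L) return("mm2_3p")
  off5 <- aln[1L] - canonical[1L]   # > 0: read starts downstream = 5' shorter
  off3 <- aln[2L] - canonical[2L]   # > 0: read ends downstream = 3' longer
  if (off5 == 0L && off3 == 0L) return("canonical")
  if (off5 != 0L && off3 == 0L) return(if (off5 > 0L) "short5p" else "long5p")
  if (off5 == 0L && off3 != 0L) return(if (off3 > 0L) "long3p" else "short3p")
  "len_both"
}

#' Name an sRNA product by field convention
#'
#' Strips the species prefix and the `mir-` stem from the precursor name:
#' miRs become `miR-X-5p/3p`, moRs `moR-X-5p/3p`, loops `loop-X`.
#'
#' @param precursor_name Precursor name, e.g. `"hsa-mir-421"`.
#' @param class One of `"mir"`, `"new_mir"`, `"mor"`, `"loop"`.
#' @param arm `"5p"`, `"3p"` or `"loop"`.
#' @return The sRNA name, e.g. `"moR-421-5p"`.
#' @export
name_srna <- function(precursor_name, class, arm) {
  core <- sub("^[A-Za-z0-9]{2,4}-", "", precursor_name)  # species prefix
  core <- sub("^[Mm][Ii][Rr]-?", "", core)
  prefix <- switch(class, mir = "miR", new_mir = "miR", mor = "moR",
                   loop = "loop")
  if (class == "loop") paste0(prefix, "-", core)
  else paste0(prefix, "-", core, "-", arm)
}

#' Aggregate assignments into isoform and sRNA expression tables
#'
#' @param assignments data.frame with one row per (sample, tag, precursor)
#'   assignment: columns `sample`, `precursor_id`, `srna`, `class`,
#'   `isoform_type`, `offset5`, `offset3`, `mm_pos`, `seq`, `count`,
#'   `cross_map`.
#' @return List with `isoforms` (the input, aggregated), `counts` (integer
#'   matrix, rows = sRNA names, columns = samples) and `row_meta`
#'   (`class`, `is_loop`, `cross_map` per row).
#' @export
quantify <- function(assignments) {
  samples <- unique(assignments$sample)
  if (!nrow(assignments)) {
    mat <- matrix(0L, nrow = 0, ncol = length(samples),
                  dimnames = list(character(0), samples))
    return(list(isoforms = assignments, counts = mat,
                row_meta = data.frame(class = character(0),
                                      is_loop = logical(0),
                                      cross_map = logical(0))))
  }
  srnas <- sort(unique(assignments$srna))
  mat <- matrix(0L, nrow = length(srnas), ncol = length(samples),
                dimnames = list(srnas, samples))
  agg <- stats::aggregate(count ~ srna + sample, data = assignments, sum)
  mat[cbind(match(agg$srna, srnas), match(agg$sample, samples))] <-
    as.integer(agg$count)
  row_meta <- data.frame(
    class = assignments$class[match(srnas, assignments$srna)],
    is_loop = assignments$class[match(srnas, assignments$srna)] == "loop",
    cross_map = vapply(srnas, function(s)
      any(assignments$cross_map[assignments$srna == s]), logical(1)),
    row.names = srnas, stringsAsFactors = FALSE)
  list(isoforms = assignments, counts = mat, row_meta = row_meta)
}

#' Counts-per-million normalization
#'
#' `value = count / sample_total * 1e6`. With `include_loops = FALSE`
#' (mirroring the removal of loop sequences from the expression matrix before
#' normalization), loop rows are dropped and the totals are computed over the
#' remaining rows, renormalizing them upward.
#'
#' @param counts Integer count matrix (rows sRNAs, columns samples).
#' @param is_loop Logical vector flagging loop rows (default none).
#' @param include_loops Keep loop rows and count them in the totals.
#' @return Numeric CPM matrix; each column sums to 1e6 (over counted rows).
#' @export
cpm_normalize <- function(counts, is_loop = rep(FALSE, nrow(counts)),
                          include_loops = FALSE) {
  if (!include_loops) counts <- counts[!is_loop, , drop = FALSE]
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total count: ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 2L, totals, "/") * 1e6
}
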