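# Extended precursors, hairpin folding, star projection, moR/loop geometry.

#' Build an extended precursor (precursor + 30 nt genomic flanks)
#'
#' The extended sequence is the genomic slice `[start - flank, end + flank)`
#' taken on the transcribed strand (reverse-complemented for minus-strand
#' precursors), with flanks truncated at contig boundaries. Annotated mature
#' intervals are converted to extended-local coordinates (0-based half-open,
#' local position 0 = transcript 5' end of the extended sequence).
#'
#' @param prec One-row data.frame (a row of `mir_annotation$precursors`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param matures data.frame of matures for this precursor (may be empty).
#' @param flank Flank length in nt (default 30).
#' @return An `extended_precursor` list: `id`, `name`, `seq`, `chrom`,
#'   `strand`, `gstart_ext` (0-based genomic start of the extended slice on
#'   the plus strand), `flank5`, `flank3`, `prec_local` (local interval of
#'   the precursor proper) and `matures` (local intervals).
#' @export
extend_precursor <- function(prec, genome, matures = NULL, flank = 30L) {
  if (!prec$chrom %in% names(genome))
    stop("precursor chromosome '", prec$chrom, "' absent from genome")
  clen <- Biostrings::width(genome[prec$chrom])
  gs <- max(0L, prec$start - flank)
  ge <- min(clen, prec$end + flank)
  slice <- as.character(Biostrings::subseq(genome[[prec$chrom]], gs + 1L, ge))
  # flanks in transcript orientation
  up_g <- prec$start - gs     # genomic left flank obtained
  dn_g <- ge - prec$end       # genomic right flank obtained
  if (prec$strand == "+") {
    seq <- slice
    flank5 <- up_g; flank3 <- dn_g
  } else {
    seq <- revcomp(slice)
    flank5 <- dn_g; flank3 <- up_g
  }
  glen <- ge - gs
  ext <- list(id = prec$id, name = prec$name, seq = seq, chrom = prec$chrom,
              strand = prec$strand, gstart_ext = gs,
              flank5 = flank5, flank3 = flank3,
              prec_local = c(flank5, glen - flank3))
  class(ext) <- "extended_precursor"
  mt <- data.frame(id = character(0), name = character(0),
                   start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
  if (!is.null(matures) && nrow(matures)) {
    loc <- t(vapply(seq_len(nrow(matures)), function(i) {
      genomic_to_local(ext, matures$start[i], matures$end[i])
    }, integer(2)))
    mt <- data.frame(id = matures$id, name = matures$name,
                     start = loc[, 1L], end = loc[, 2L],
                     stringsAsFactors = FALSE)
  }
  ext$matures <- mt
  ext
}

#' Convert a genomic interval to extended-local coordinates
#' @param ext An `extended_precursor`.
#' @param gstart,gend 0-based half-open genomic interval.
#' @return Integer `c(start, end)` in extended-local coordinates.
#' @export
genomic_to_local <- function(ext, gstart, gend) {
  glen <- nchar(ext$seq)
  if (ext$strand == "+") {
    c(gstart - ext$gstart_ext, gend - ext$gstart_ext)
  } else {
    c(ext$gstart_ext + glen - gend, ext$gstart_ext + glen - gstart)
  }
}

#' Fold a sequence into its maximum base-pair hairpin structure
#'
#' The built-in folder maximizes Watson-Crick plus G:U base pairs with a
#' minimum loop of 3 unpaired bases (dynamic programming, deterministic
#' traceback). Only the pairing topology is consumed downstream (star
#' projection), so base-pair maximization stands in for a thermodynamic
#' folder; a pre-computed dot-bracket (e.g. from an external MFE folder) can
#' be supplied instead via `structure` and is validated against the same
#' invariants.
#'
#' @param seq DNA/RNA sequence (length >= 10 for the built-in folder).
#' @param structure Optional externally computed dot-bracket string.
#' @return A `fold_result` list: `db` (dot-bracket) and `pairs` (integer
#'   vector, `pairs[i]` is the 1-based partner of position `i`, `NA` if
#'   unpaired).
#' @export
fold_hairpin <- function(seq, structure = NULL) {
  seq <- toupper(seq)
  if (is.null(structure)) {
    if (nchar(seq) < 10L) stop("sequence too short to fold (< 10 nt)")
    db <- nussinov_db(seq)
  } else {
    if (nchar(structure) != nchar(seq))
      stop("external dot-bracket length differs from sequence length")
    db <- structure
  }
  pairs <- parse_dot_bracket(db)
  structure(list(db = db, pairs = pairs), class = "fold_result")
}

#' Parse and validate a dot-bracket string
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @return Integer pair-table vector (`NA` = unpaired). Errors on unbalanced
#'   brackets, foreign characters, or pairs violating the minimum loop of 3.
#' @export
parse_dot_bracket <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket character")
  pairs <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (i - j < 4L) stop("dot-bracket violates minimum loop size 3")
      pairs[j] <- i
      pairs[i] <- j
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket: unmatched '('")
  pairs
}

#' Project the complementary (star) sequence of a mature miRNA
#'
#' The star interval is the span of the pairing partners of the mature's
#' paired positions, shifted by the canonical 2-nt 3' overhang of the
#' Drosha/Dicer duplex. Returns `NULL` when fewer than `min_paired_frac` of
#' the mature positions are paired (no hairpin support) or when the projected
#' star overlaps an annotated mature by more than `max_mature_overlap` nt.
#'
#' @param mature Integer `c(start, end)`, extended-local 0-based half-open.
#' @param fold A [fold_hairpin()] result for the extended precursor.
#' @param matures Optional data.frame of annotated mature local intervals
#'   (used for the overlap veto).
#' @param min_paired_frac Minimum fraction of paired mature positions
#'   (default 0.6).
#' @param overhang Duplex 3' overhang in nt (default 2).
#' @param max_mature_overlap Maximum tolerated overlap with an annotated
#'   mature in nt (default 3).
#' @return Integer `c(start, end)` or `NULL`.
#' @export
project_star <- function(mature, fold, matures = NULL, min_paired_frac = 0.6,
                         overhang = 2L, max_mature_overlap = 3L) {
  idx <- (mature[1L] + 1L):mature[2L]           # 1-based positions
  partners <- fold$pairs[idx]
  paired <- !is.na(partners)
  if (mean(paired) < min_paired_frac) return(NULL)
  lo <- min(partners[paired]) - 1L              # back to 0-based
  hi <- max(partners[paired])                   # half-open end
  star <- c(lo + overhang, hi + overhang)
  n <- length(fold$pairs)
  star <- pmin(pmax(star, 0L), n)
  if (star[2L] - star[1L] < 1L) return(NULL)
  if (!is.null(matures) && nrow(matures)) {
    ov <- pmin(star[2L], matures$end) - pmax(star[1L], matures$start)
    if (any(ov > max_mature_overlap)) return(NULL)
  }
  as.integer(star)
}

#' Candidate moRNA windows and loop interval
#'
#' moRNAs arise from the precursor regions immediately adjacent to the arm
#' products; miRs and their adjacent moRs may overlap in a few terminal bases
#' (`overlap_slack`, 3 nt).
#'
#' @param mir5p,mir3p Local intervals of the 5p/3p arm products (annotation
#'   or star projection), or `NULL` if the arm is undefined.
#' @param ext_len Length of the extended precursor sequence.
#' @param overlap_slack Tolerated miR/moR terminal overlap in nt (default 3).
#' @return List with `mor5p_window`, `mor3p_window` and `loop` intervals
#'   (each `NULL` when the defining arm(s) are missing).
#' @export
mor_geometry <- function(mir5p, mir3p, ext_len, overlap_slack = 3L) {
  w5 <- if (!is.null(mir5p)) c(0L, mir5p[1L] + overlap_slack) else NULL
  w3 <- if (!is.null(mir3p)) c(mir3p[2L] - overlap_slack, as.integer(ext_len)) else NULL
  loop <- NULL
  if (!is.null(mir5p) && !is.null(mir3p) && mir3p[1L] > mir5p[2L]) {
    loop <- c(mir5p[2L], mir3p[1L])
  }
  list(mor5p_window = w5, mor3p_window = w3, loop = loop)
}

#' Read per-precursor external fold structures from a 2-column TSV
#' @param path TSV with columns precursor id, dot-bracket (no header).
#' @return Named character vector of dot-bracket strings.
#' @export
read_fold_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("id", "structure"))
  stats::setNames(df$structure, df$id)
}
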