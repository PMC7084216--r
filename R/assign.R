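# Tag-to-precursor alignment, alignment blocks, sRNA finalization and
# read assignment.

#' Assignment parameters
#'
#' Config-key spellings: `ALLOWED_OVERHANG`, `MIN_MORNA_LEN`, `MORFILTER`.
#'
#' @param allowed_overhang Maximum distance (nt) between an alignment end and
#'   the sRNA end for the alignment to be assignable (default 3).
#' @param min_morna_len Minimum moRNA length in nt (default 16).
#' @param morfilter `"conservative"` removes moRNAs sharing sequence with any
#'   miR in the catalog; `"permissive"` keeps them (default conservative).
#' @return An `assign_params` list.
#' @export
assign_params <- function(allowed_overhang = 3L, min_morna_len = 16L,
                          morfilter = c("conservative", "permissive")) {
  morfilter <- match.arg(morfilter)
  stopifnot(allowed_overhang >= 0L, min_morna_len >= 1L)
  structure(list(allowed_overhang = as.integer(allowed_overhang),
                 min_morna_len = as.integer(min_morna_len),
                 morfilter = morfilter),
            class = "assign_params")
}

#' Align a tag to an extended precursor allowing mismatches
#'
#' All placements with Hamming distance <= `max_mm` are computed and only the
#' best stratum is reported (all 0-mismatch placements if any exist, else all
#' 1-mismatch, else all 2-mismatch) - the best/strata contract of a
#' stratified short-read aligner.
#'
#' @param tagseq Tag sequence.
#' @param ext An `extended_precursor` (or any character sequence).
#' @param max_mm Maximum mismatches (default 2).
#' @return data.frame with `start`, `end` (local 0-based half-open), `mm`,
#'   and `mm_pos` (comma-separated read-relative 0-based mismatch positions,
#'   `""` if none). Zero rows if the tag does not align.
#' @export
align_to_precursor <- function(tagseq, ext, max_mm = 2L) {
  refseq <- if (inherits(ext, "extended_precursor")) ext$seq else ext
  l <- nchar(tagseq)
  empty <- data.frame(start = integer(0), end = integer(0), mm = integer(0),
                      mm_pos = character(0), stringsAsFactors = FALSE)
  if (l > nchar(refseq)) return(empty)
  mmv <- hamming_counts(tagseq, refseq)
  hit <- which(mmv <= max_mm)
  if (!length(hit)) return(empty)
  best <- min(mmv[hit])
  hit <- hit[mmv[hit] == best]
  starts <- hit - 1L
  mm_pos <- character(length(hit))
  if (best > 0L) {
    tagch <- strsplit(tagseq, "")[[1L]]
    refch <- strsplit(refseq, "")[[1L]]
    for (k in seq_along(hit)) {
      o <- starts[k]
      mis <- which(tagch != refch[(o + 1L):(o + l)]) - 1L
      mm_pos[k] <- paste(mis, collapse = ",")
    }
  }
  data.frame(start = starts, end = starts + l, mm = mmv[hit],
             mm_pos = mm_pos, stringsAsFactors = FALSE)
}

#' Filter 2-mismatch alignments to 3'-terminal mismatches only
#'
#' Alignments with exactly two mismatches are kept only when both mismatches
#' occupy the two 3'-terminal read positions (`len-2`, `len-1`), accounting
#' for post-transcriptional nucleotide addition. 0- and 1-mismatch
#' alignments pass unconditionally.
#'
#' @param alns Alignment data.frame from [align_to_precursor()].
#' @return Logical keep vector.
#' @export
filter_two_mismatch_3prime <- function(alns) {
  if (!nrow(alns)) return(logical(0))
  len <- alns$end - alns$start
  keep <- alns$mm < 2L
  two <- which(alns$mm == 2L)
  for (i in two) {
    pos <- as.integer(strsplit(alns$mm_pos[i], ",")[[1L]])
    keep[i] <- setequal(pos, c(len[i] - 2L, len[i] - 1L))
  }
  keep
}

#' Build non-overlapping alignment blocks from perfect alignments
#'
#' Greedy clustering by descending tag count (ties: longer tag, then leftmost
#' start, then lexicographic sequence). The highest-count unclustered tag
#' seeds a block with its own interval (the block representative); any
#' alignment overlapping the seed interval by more than half of its own
#' length joins the block. A later seed overlapping an earlier block's seed
#' by more than half of its own length is merged into that block; adjacent
#' products (e.g. a moR overlapping its miR by a few terminal bases) remain
#' separate blocks.
#'
#' @param alns data.frame of 0-mismatch alignments of one precursor with
#'   columns `seq`, `count`, `start`, `end`.
#' @return data.frame of blocks: `block_id`, `start`, `end` (representative
#'   interval), `rep_seq`, `total_count`, `n_members`; plus a `members`
#'   attribute giving each input row's block id.
#' @export
build_blocks <- function(alns) {
  empty <- data.frame(block_id = integer(0), start = integer(0),
                      end = integer(0), rep_seq = character(0),
                      total_count = integer(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(alns)) {
    attr(empty, "members") <- integer(0)
    return(empty)
  }
  ord <- order(-alns$count, -(alns$end - alns$start), alns$start, alns$seq)
  member <- rep(NA_integer_, nrow(alns))
  blocks <- list()
  for (i in ord) {
    if (!is.na(member[i])) next
    seed <- c(alns$start[i], alns$end[i])
    seed_len <- seed[2L] - seed[1L]
    # merge into an earlier block whose seed this one mostly overlaps
    merged <- FALSE
    for (b in seq_along(blocks)) {
      bs <- blocks[[b]]$interval
      ov <- min(seed[2L], bs[2L]) - max(seed[1L], bs[1L])
      if (ov > 0.5 * seed_len) {
        member[i] <- b
        merged <- TRUE
        break
      }
    }
    if (merged) next
    bid <- length(blocks) + 1L
    member[i] <- bid
    # join all unclustered alignments overlapping the seed by > 50% of
    # their own length
    free <- which(is.na(member))
    if (length(free)) {
      ov <- pmin(alns$end[free], seed[2L]) - pmax(alns$start[free], seed[1L])
      join <- free[ov > 0.5 * (alns$end[free] - alns$start[free])]
      member[join] <- bid
    }
    blocks[[bid]] <- list(interval = seed, rep = i)
  }
  out <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    rows <- which(member == b)
    data.frame(block_id = b,
               start = blocks[[b]]$interval[1L],
               end = blocks[[b]]$interval[2L],
               rep_seq = alns$seq[blocks[[b]]$rep],
               total_count = sum(alns$count[rows]),
               n_members = length(rows), stringsAsFactors = FALSE)
  }))
  attr(out, "members") <- member
  out
}

class_rank <- c(mir = 1L, new_mir = 2L, mor = 3L, loop = 4L)
arm_rank <- c("5p" = 1L, "3p" = 2L, loop = 3L)

#' Finalize the sRNA definitions of one precursor
#'
#' From the precursor's alignment blocks: (i) an annotated mature is
#' "expressed" iff some block representative matches it within
#' `allowed_overhang` at both ends; (ii) a block matching the star-projected
#' interval (same tolerance) defines a `new_mir`; (iii) a remaining block
#' whose representative lies inside a moR window and is at least
#' `min_morna_len` long defines a moR (coordinates = the representative
#' interval, i.e. data-driven); (iv) a block inside the loop interval defines
#' the loop sRNA. At most one definition per (class, arm); the
#' highest-count block wins.
#'
#' @param ext An `extended_precursor`.
#' @param fold Fold of the extended sequence.
#' @param blocks Block table from [build_blocks()].
#' @param params An [assign_params()] object.
#' @param star_cfg Optional list overriding [project_star()] settings
#'   (`min_paired_frac`, `overhang`, `max_mature_overlap`).
#' @return data.frame of sRNA definitions: `precursor_id`, `precursor_name`,
#'   `class`, `arm`, `start`, `end`, `name`, `seq`, `support_count`.
#' @export
finalize_srnas <- function(ext, fold, blocks, params = assign_params(),
                           star_cfg = list()) {
  defs <- list()
  ao <- params$allowed_overhang
  ext_len <- nchar(ext$seq)
  hairpin_mid <- mean(ext$prec_local)
  arm_of <- function(iv) if (mean(iv) < hairpin_mid) "5p" else "3p"
  match_block <- function(iv) {
    if (!nrow(blocks)) return(NULL)
    ok <- abs(blocks$start - iv[1L]) <= ao & abs(blocks$end - iv[2L]) <= ao
    if (!any(ok)) return(NULL)
    cand <- blocks[ok, , drop = FALSE]
    cand[which.max(cand$total_count), , drop = FALSE]
  }
  add_def <- function(class, arm, iv, support) {
    defs[[length(defs) + 1L]] <<- data.frame(
      precursor_id = ext$id, precursor_name = ext$name,
      class = class, arm = arm, start = iv[1L], end = iv[2L],
      name = name_srna(ext$name, class, arm),
      seq = substr(ext$seq, iv[1L] + 1L, iv[2L]),
      support_count = support, stringsAsFactors = FALSE)
  }

  arms <- list(`5p` = NULL, `3p` = NULL)   # defining interval per arm
  used_blocks <- integer(0)

  # (i) annotated matures
  if (nrow(ext$matures)) {
    for (i in seq_len(nrow(ext$matures))) {
      iv <- c(ext$matures$start[i], ext$matures$end[i])
      arm <- arm_of(iv)
      if (is.null(arms[[arm]])) arms[[arm]] <- iv
      b <- match_block(iv)
      if (!is.null(b)) {
        add_def("mir", arm, iv, b$total_count)
        used_blocks <- c(used_blocks, b$block_id)
      }
    }
  }

  # (ii) star projections -> new miRNAs
  if (nrow(ext$matures)) {
    for (i in seq_len(nrow(ext$matures))) {
      iv <- c(ext$matures$start[i], ext$matures$end[i])
      star <- do.call(project_star, c(list(mature = iv, fold = fold,
                                           matures = ext$matures), star_cfg))
      if (is.null(star)) next
      arm <- arm_of(star)
      if (is.null(arms[[arm]])) arms[[arm]] <- star
      b <- match_block(star)
      if (!is.null(b) && !any(vapply(defs, function(d)
            d$class %in% c("mir", "new_mir") && d$arm == arm, logical(1)))) {
        add_def("new_mir", arm, star, b$total_count)
        used_blocks <- c(used_blocks, b$block_id)
      }
    }
  }

  # (iii) moRNAs and (iv) loop from the remaining blocks
  geom <- mor_geometry(arms[["5p"]], arms[["3p"]], ext_len)
  remaining <- blocks[!blocks$block_id %in% used_blocks, , drop = FALSE]
  pick_best <- function(w, min_len = 1L) {
    if (is.null(w) || !nrow(remaining)) return(NULL)
    ok <- remaining$start >= w[1L] & remaining$end <= w[2L] &
      (remaining$end - remaining$start) >= min_len
    if (!any(ok)) return(NULL)
    cand <- remaining[ok, , drop = FALSE]
    cand[which.max(cand$total_count), , drop = FALSE]
  }
  b <- pick_best(geom$mor5p_window, params$min_morna_len)
  if (!is.null(b)) add_def("mor", "5p", c(b$start, b$end), b$total_count)
  b <- pick_best(geom$mor3p_window, params$min_morna_len)
  if (!is.null(b)) add_def("mor", "3p", c(b$start, b$end), b$total_count)
  b <- pick_best(geom$loop)
  if (!is.null(b)) add_def("loop", "loop", c(b$start, b$end), b$total_count)

  if (!length(defs)) {
    return(data.frame(precursor_id = character(0), precursor_name = character(0),
                      class = character(0), arm = character(0),
                      start = integer(0), end = integer(0), name = character(0),
                      seq = character(0), support_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, defs)
  out <- out[order(class_rank[out$class], arm_rank[out$arm]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conservative moRNA sequence filter
#'
#' In `"conservative"` mode a moRNA is removed from the catalog when its
#' sequence is shared with any miR: the moR sequence occurs as a substring of
#' any miR/new_mir sequence anywhere in the catalog, or vice versa.
#' `"permissive"` mode is the identity.
#'
#' @param defs Catalog data.frame (all precursors) from [finalize_srnas()].
#' @param mode `"conservative"` or `"permissive"`.
#' @return Filtered catalog data.frame.
#' @export
mor_sequence_filter <- function(defs, mode = c("conservative", "permissive")) {
  mode <- match.arg(mode)
  if (mode == "permissive" || !nrow(defs)) return(defs)
  mir_seqs <- defs$seq[defs$class %in% c("mir", "new_mir")]
  if (!length(mir_seqs)) return(defs)
  is_mor <- defs$class == "mor"
  shared <- vapply(seq_len(nrow(defs)), function(i) {
    if (!is_mor[i]) return(FALSE)
    s <- defs$seq[i]
    any(vapply(mir_seqs, function(m)
      grepl(s, m, fixed = TRUE) || grepl(m, s, fixed = TRUE), logical(1)))
  }, logical(1))
  out <- defs[!shared, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign one alignment to an sRNA definition
#'
#' Assignable iff each alignment end lies within `allowed_overhang` of the
#' sRNA's corresponding end; among assignable sRNAs the one with maximal
#' reciprocal overlap wins, ties broken by class precedence
#' mir > new_mir > mor > loop, then 5p before 3p.
#'
#' @param aln Integer `c(start, end)` of the alignment (local).
#' @param defs sRNA definition data.frame of the alignment's precursor.
#' @param params An [assign_params()] object.
#' @return Row index into `defs`, or `NA_integer_` (unassigned).
#' @export
assign_alignment <- function(aln, defs, params = assign_params()) {
  if (!nrow(defs)) return(NA_integer_)
  ao <- params$allowed_overhang
  ok <- abs(aln[1L] - defs$start) <= ao & abs(aln[2L] - defs$end) <= ao
  if (!any(ok)) return(NA_integer_)
  idx <- which(ok)
  la <- aln[2L] - aln[1L]
  ov <- pmin(aln[2L], defs$end[idx]) - pmax(aln[1L], defs$start[idx])
  ov <- pmax(ov, 0L)
  score <- pmin(ov / la, ov / (defs$end[idx] - defs$start[idx]))
  best <- order(-score, class_rank[defs$class[idx]], arm_rank[defs$arm[idx]])[1L]
  idx[best]
}
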