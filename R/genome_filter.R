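# Exact multi-locus genome matching and the multi-mapping discard rule.

#' Multi-mapping parameters
#'
#' @param max_hits_enumerated Cap on enumerated genome hits per tag (default
#'   50). Any cap greater than `max_outside_loci` plus the precursor
#'   multiplicity leaves the discard decision unchanged.
#' @param max_outside_loci Maximum tolerated exact hits outside known or
#'   predicted miRNA precursor loci; strictly more triggers discard
#'   (default 5, i.e. "> 5" discards).
#' @return A `multimap_params` list.
#' @export
multimap_params <- function(max_hits_enumerated = 50L, max_outside_loci = 5L) {
  stopifnot(max_hits_enumerated > max_outside_loci, max_outside_loci >= 0L)
  structure(list(max_hits_enumerated = as.integer(max_hits_enumerated),
                 max_outside_loci = as.integer(max_outside_loci)),
            class = "multimap_params")
}

#' Build an exact-match genome index
#'
#' Supports all-occurrence exact lookup of 15-35 nt queries on both strands;
#' hits are labelled by strand-aware overlap with the precursor intervals
#' (known annotation plus any extra predicted precursors).
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param precursors data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `strand`; the union of known and extra precursor loci.
#' @return A `genome_index` object.
#' @export
build_genome_index <- function(genome, precursors) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  structure(list(genome = genome, precursors = precursors),
            class = "genome_index")
}

#' Locate all exact genome occurrences of a tag
#'
#' Both strands are searched (reverse complement for the minus strand).
#' Enumeration is capped at `max_hits_enumerated`; when more hits exist the
#' result carries `capped = TRUE`. Each hit is labelled `inside_precursor`
#' iff it overlaps (non-empty, half-open intersection) a precursor interval
#' on the same strand.
#'
#' @param tagseq Tag DNA sequence.
#' @param index A [build_genome_index()] object.
#' @param params A [multimap_params()] object.
#' @return data.frame of hits (`chrom`, `start`, `end`, `strand`,
#'   `inside_precursor`) with attribute `capped`.
#' @export
locate_tag <- function(tagseq, index, params = multimap_params()) {
  hits <- list()
  for (chrom in names(index$genome)) {
    subj <- index$genome[[chrom]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") tagseq else revcomp(tagseq)
      m <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
      if (length(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom,
          start = BiocGenerics::start(m) - 1L,
          end = BiocGenerics::end(m),
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  capped <- nrow(hits) > params$max_hits_enumerated
  if (capped) hits <- hits[seq_len(params$max_hits_enumerated), , drop = FALSE]
  hits$inside_precursor <- overlaps_precursor(hits, index$precursors)
  attr(hits, "capped") <- capped
  hits
}

overlaps_precursor <- function(hits, precursors) {
  if (!nrow(hits)) return(logical(0))
  out <- logical(nrow(hits))
  if (is.null(precursors) || !nrow(precursors)) return(out)
  for (i in seq_len(nrow(hits))) {
    out[i] <- any(precursors$chrom == hits$chrom[i] &
                    precursors$strand == hits$strand[i] &
                    precursors$start < hits$end[i] &
                    precursors$end > hits$start[i])
  }
  out
}

#' Multi-mapping discard rule
#'
#' A tag is discarded iff it has strictly more than `max_outside_loci` exact
#' hits outside precursor loci, or hit enumeration was capped. Tags with zero
#' genome hits are kept and flagged `genome_unmapped`: they may still carry
#' non-templated 3' additions and align to a precursor with mismatches.
#'
#' @param hits Hit table from [locate_tag()].
#' @param params A [multimap_params()] object.
#' @return List with logical `keep`, logical `genome_unmapped`, and integer
#'   `n_outside`.
#' @export
multimap_filter <- function(hits, params = multimap_params()) {
  n_outside <- sum(!hits$inside_precursor)
  capped <- isTRUE(attr(hits, "capped"))
  keep <- !capped && n_outside <= params$max_outside_loci
  list(keep = keep, genome_unmapped = nrow(hits) == 0L,
       n_outside = n_outside)
}

#' Apply the genome filter to a tag table
#'
#' @param tags data.frame with `seq` and `count`.
#' @param index A [build_genome_index()] object.
#' @param params A [multimap_params()] object.
#' @return List with `tags` (kept, plus `genome_unmapped` flag column),
#'   `discarded` (tag table), and `stats`.
#' @export
filter_tags_genome <- function(tags, index, params = multimap_params()) {
  n <- nrow(tags)
  keep <- logical(n)
  unmapped <- logical(n)
  for (i in seq_len(n)) {
    h <- locate_tag(tags$seq[i], index, params)
    f <- multimap_filter(h, params)
    keep[i] <- f$keep
    unmapped[i] <- f$genome_unmapped
  }
  kept <- tags[keep, , drop = FALSE]
  kept$genome_unmapped <- unmapped[keep]
  rownames(kept) <- NULL
  list(tags = kept, discarded = tags[!keep, , drop = FALSE],
       stats = list(n_in = n, n_kept = sum(keep),
                    n_multimap_discarded = sum(!keep),
                    n_genome_unmapped = sum(unmapped & keep)))
}
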