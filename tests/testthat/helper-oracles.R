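# Independent oracles used to cross-check the implementation paths.

# Brute-force Hamming scan: every placement of tag on ref with <= max_mm
# mismatches, as a data.frame(start, mm) in 0-based coordinates.
oracle_hamming_scan <- function(tag, ref, max_mm = 2L) {
  tagc <- strsplit(tag, "")[[1L]]
  refc <- strsplit(ref, "")[[1L]]
  l <- length(tagc)
  n <- length(refc)
  out <- list()
  if (l <= n) {
    for (o in 0:(n - l)) {
      mm <- sum(tagc != refc[(o + 1L):(o + l)])
      if (mm <= max_mm) out[[length(out) + 1L]] <- c(o, mm)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), mm = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], mm = m[, 2L])
}

oracle_can_pair <- function(a, b) {
  p <- paste0(a, b)
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG", "AU", "UA", "GU", "UG")
}

# Maximum number of nested base pairs (Watson-Crick + G:U, min loop 3),
# evaluated as the top-down recurrence in R with memoisation. Independent of
# the compiled bottom-up DP + traceback it checks.
oracle_max_pairs <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1L]]
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (oracle_can_pair(s[i], s[k])) {
        v <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 5L) return(0L)
  rec(1L, n)
}

# Brute-force exact genome scan on both strands; genome is a named character
# vector. Returns data.frame(chrom, start, end, strand), 0-based half-open.
oracle_genome_hits <- function(tag, genome) {
  out <- list()
  rc <- moRquant::revcomp(tag)
  l <- nchar(tag)
  for (chrom in names(genome)) {
    seqc <- genome[[chrom]]
    n <- nchar(seqc)
    if (l > n) next
    for (o in 0:(n - l)) {
      w <- substr(seqc, o + 1L, o + l)
      if (w == tag)
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = o,
                                              end = o + l, strand = "+")
      if (w == rc)
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = o,
                                              end = o + l, strand = "-")
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  do.call(rbind, out)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# An idealized perfect hairpin fold (stem S, loop L, optional flanks) built
# directly from the dot-bracket string, bypassing the folder.
perfect_fold <- function(stem, loop, flank = 0L) {
  db <- paste0(strrep(".", flank), strrep("(", stem), strrep(".", loop),
               strrep(")", stem), strrep(".", flank))
  structure(list(db = db, pairs = moRquant::parse_dot_bracket(db)),
            class = "fold_result")
}
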