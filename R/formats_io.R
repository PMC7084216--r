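# File format I/O and the single coordinate-conversion boundary.
#
# Internal convention: 0-based half-open intervals on the transcribed strand.
# GFF3 is 1-based inclusive genomic; conversion happens only in this file's
# readers/writers and in local_to_genomic()/genomic slice helpers.

#' Read a (possibly gzipped) 4-line FASTQ file
#'
#' @param path Path to a FASTQ file, plain or gzip-compressed.
#' @return A data.frame with columns `id`, `seq` (uppercase) and `qual`
#'   (Phred+33 string of the same length), one row per read, in file order.
#' @details Malformed records (missing `@`/`+` marker, sequence/quality length
#'   mismatch, truncated record) raise an error naming the offending line.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ", (n %/% 4L) * 4L + 1L,
         " in ", path)
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seq <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1L]],
         ": record header must start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1L]] + 2L,
         ": separator line must start with '+'")
  }
  bad <- which(nchar(seq) != nchar(qual) | nchar(seq) < 1L)
  if (length(bad)) {
    stop("FASTQ parse error at line ", idx[bad[1L]] + 1L,
         ": sequence and quality lengths differ (or empty sequence)")
  }
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to a 4-line FASTQ file
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads)) {
    out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  } else {
    out <- character(0)
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#' @param path Path to a (multi-)FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicated sequence names in ", path)
  if (any(Biostrings::width(g) == 0L)) stop("empty sequence in ", path)
  g
}

#' Read a miRBase-dialect miRNA annotation from GFF3
#'
#' Parses `miRNA_primary_transcript` (precursor) and `miRNA` (mature)
#' features. Mature-to-precursor linkage uses the `Derives_from` attribute
#' when present, falling back to same-strand containment; a mature contained
#' in several precursors is linked to all of them (multi-locus miRNAs).
#' Matures with no resolvable parent are dropped with a warning.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @return A list with class `mir_annotation`: `precursors` and `matures`
#'   data.frames with 0-based half-open `start`/`end` columns; `matures`
#'   carries a `precursor_id` column.
#' @export
read_mir_gff3 <- function(path) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  grp <- gr[type == "miRNA_primary_transcript"]
  grm <- gr[type == "miRNA"]
  get_attr <- function(x, field) {
    v <- S4Vectors::mcols(x)[[field]]
    if (is.null(v)) return(rep(NA_character_, length(x)))
    if (methods::is(v, "List") || is.list(v)) {
      v <- vapply(v, function(e) if (length(e)) as.character(e[[1L]]) else NA_character_,
                  character(1))
    }
    as.character(v)
  }
  pid <- get_attr(grp, "ID")
  if (anyNA(pid)) pid[is.na(pid)] <- get_attr(grp, "Name")[is.na(pid)]
  precursors <- data.frame(
    id = pid,
    name = ifelse(is.na(get_attr(grp, "Name")), pid, get_attr(grp, "Name")),
    chrom = as.character(GenomeInfoDb::seqnames(grp)),
    start = BiocGenerics::start(grp) - 1L,
    end = BiocGenerics::end(grp),
    strand = as.character(BiocGenerics::strand(grp)),
    stringsAsFactors = FALSE
  )
  mid <- get_attr(grm, "ID")
  mname <- get_attr(grm, "Name")
  mfrom <- get_attr(grm, "Derives_from")
  matures <- data.frame(
    id = ifelse(is.na(mid), mname, mid),
    name = ifelse(is.na(mname), mid, mname),
    chrom = as.character(GenomeInfoDb::seqnames(grm)),
    start = BiocGenerics::start(grm) - 1L,
    end = BiocGenerics::end(grm),
    strand = as.character(BiocGenerics::strand(grm)),
    derives_from = mfrom,
    stringsAsFactors = FALSE
  )
  # resolve linkage
  rows <- vector("list", nrow(matures))
  for (i in seq_len(nrow(matures))) {
    m <- matures[i, ]
    parent <- character(0)
    if (!is.na(m$derives_from) && m$derives_from %in% precursors$id) {
      parent <- m$derives_from
    } else {
      hit <- precursors$chrom == m$chrom & precursors$strand == m$strand &
        precursors$start <= m$start & precursors$end >= m$end
      parent <- precursors$id[hit]
    }
    if (!length(parent)) {
      warning("mature '", m$id, "' has no resolvable parent precursor; dropped")
      next
    }
    rows[[i]] <- data.frame(m[rep(1L, length(parent)),
                              c("id", "name", "chrom", "start", "end", "strand")],
                            precursor_id = parent, stringsAsFactors = FALSE)
  }
  matures <- do.call(rbind, rows)
  if (is.null(matures)) {
    matures <- data.frame(id = character(0), name = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          precursor_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(matures) <- NULL
  # invariant: mature within its parent and on the same strand
  if (nrow(matures)) {
    pi <- match(matures$precursor_id, precursors$id)
    ok <- matures$strand == precursors$strand[pi] &
      matures$start >= precursors$start[pi] & matures$end <= precursors$end[pi]
    if (any(!ok)) {
      warning(sum(!ok), " mature record(s) outside their parent precursor; dropped")
      matures <- matures[ok, , drop = FALSE]
    }
  }
  structure(list(precursors = precursors, matures = matures),
            class = "mir_annotation")
}

#' Convert extended-precursor local coordinates to genomic coordinates
#'
#' @param ext An `extended_precursor` (see [extend_precursor()]).
#' @param start,end 0-based half-open interval in extended-local coordinates.
#' @return Integer vector `c(start, end)`, 0-based half-open on the genomic
#'   plus strand.
#' @export
local_to_genomic <- function(ext, start, end) {
  glen <- nchar(ext$seq)
  if (ext$strand == "+") {
    c(ext$gstart_ext + start, ext$gstart_ext + end)
  } else {
    c(ext$gstart_ext + glen - end, ext$gstart_ext + glen - start)
  }
}

#' Write the predicted sRNA catalog as GFF3
#'
#' @param catalog data.frame with columns `chrom`, `gstart`, `gend` (0-based
#'   half-open genomic), `strand`, `name`, `class`, `precursor_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_srna_gff3 <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(catalog)) {
    attrs <- paste0("ID=", catalog$name, ";Name=", catalog$name,
                    ";class=", catalog$class,
                    ";Derives_from=", catalog$precursor_id)
    writeLines(paste(catalog$chrom, "moRquant", "sRNA",
                     catalog$gstart + 1L, catalog$gend, ".",
                     catalog$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Read back an sRNA catalog written by [write_srna_gff3()]
#' @param path Path to the catalog GFF3.
#' @return data.frame with 0-based half-open genomic intervals.
#' @export
read_srna_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  cls <- S4Vectors::mcols(gr)[["class"]]
  if (is.null(cls)) cls <- rep(NA_character_, length(gr))
  df <- S4Vectors::mcols(gr)[["Derives_from"]]
  if (methods::is(df, "List") || is.list(df)) {
    df <- vapply(df, function(e) if (length(e)) as.character(e[[1L]]) else NA_character_,
                 character(1))
  }
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    gstart = BiocGenerics::start(gr) - 1L,
    gend = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    name = as.character(gr$Name),
    class = as.character(cls),
    precursor_id = as.character(df),
    stringsAsFactors = FALSE
  )
}

#' Write all per-run output files
#'
#' Writes (a) the predicted sRNA catalog as genomic GFF3, (b) the per-isoform
#' TSV, (c) the per-sRNA count matrix TSV (rows sRNAs, columns samples) and
#' (d) the unassigned-sequence TSV. All tables are tab-separated with a header
#' row and no quoting.
#'
#' @param results A `morna_results` object from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    catalog = file.path(outdir, "srna_catalog.gff3"),
    isoforms = file.path(outdir, "isoforms.tsv"),
    matrix = file.path(outdir, "srna_counts.tsv"),
    unassigned = file.path(outdir, "unassigned.tsv")
  )
  write_srna_gff3(results$catalog, paths[["catalog"]])
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(results$isoforms, paths[["isoforms"]])
  mat <- results$counts
  out <- data.frame(srna = rownames(mat), class = results$row_meta$class,
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  wt(out, paths[["matrix"]])
  wt(results$unassigned, paths[["unassigned"]])
  invisible(paths)
}

#' Reverse-complement a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
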