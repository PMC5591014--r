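#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that tokenizes record
#' headers at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

## Shared validated tabular reader for BED-like text: returns the data lines
## (track/browser/# lines skipped) split into fields, with original line
## numbers for diagnostics.
read_bedlike_lines <- function(path, min_fields) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < min_fields)
  if (length(bad)) {
    stop("malformed line ", lineno[bad[1]], " in ", path,
         ": expected >= ", min_fields, " tab-separated fields", call. = FALSE)
  }
  list(fields = fields, lineno = lineno)
}

parse_bed_coords <- function(parsed, path) {
  chrom <- vapply(parsed$fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parsed$fields, `[[`,
                                              character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parsed$fields, `[[`,
                                            character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("malformed interval at line ", parsed$lineno[bad[1]], " in ", path,
         ": need 0 <= start < end", call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Read an interval set from BED
#'
#' BED3+ parsed as 0-based half-open; `track`, `browser` and `#` lines are
#' skipped; malformed lines (fewer than three fields, non-numeric or
#' `start >= end` coordinates) raise an error naming the offending line.
#' Output is sorted by (chrom, start, end).
#'
#' @param path Path to a BED file.
#' @return A `data.frame` with `chrom`, `start`, `end` (and `name` when a
#'   fourth column is present).
#' @export
read_intervals <- function(path) {
  parsed <- read_bedlike_lines(path, 3L)
  df <- parse_bed_coords(parsed, path)
  if (all(vapply(parsed$fields, length, integer(1)) >= 4L)) {
    df$name <- vapply(parsed$fields, `[[`, character(1), 4L)
  }
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Write an interval set as BED
#'
#' @param intervals Data frame with `chrom`, `start`, `end` and optionally
#'   `name`/`score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value; 0-based
#'   half-open).
#' @return A `data.frame` with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  parsed <- read_bedlike_lines(path, 4L)
  df <- parse_bed_coords(parsed, path)
  df$score <- as.numeric(vapply(parsed$fields, `[[`, character(1), 4L))
  if (anyNA(df$score)) {
    stop("non-numeric score in ", path, call. = FALSE)
  }
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write a bedGraph signal track
#'
#' @param track Data frame with `chrom`, `start`, `end`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "score")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Reference-consumed length of a CIGAR string (M/D/N/=/X consume reference).
cigar_ref_span <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) return(NA_integer_)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Read aligned reads from minimal SAM or BED6
#'
#' SAM: header lines (`@`) skipped; strand from FLAG bit 0x10; unmapped
#' records (FLAG 0x4) skipped and counted; alignment span from 1-based POS
#' plus the reference-consuming CIGAR operations (M/D/N/=/X), converted to
#' 0-based half-open. Mapped records with CIGAR `*` are skipped with a
#' warning count. BED6 columns chrom/start/end/name/score/strand are taken
#' verbatim.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension: `.sam` vs `.bed`), `"sam"` or
#'   `"bed6"`.
#' @return A `data.frame` with `chrom`, `start`, `end`, `strand`; attribute
#'   `skipped` counts unmapped / unparseable records.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bed6")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed6"
  }
  if (format == "bed6") {
    parsed <- read_bedlike_lines(path, 6L)
    df <- parse_bed_coords(parsed, path)
    df$strand <- vapply(parsed$fields, `[[`, character(1), 6L)
    if (!all(df$strand %in% c("+", "-"))) {
      stop("BED6 strand must be + or - in ", path, call. = FALSE)
    }
    attr(df, "skipped") <- 0L
    return(df)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  skipped <- 0L
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
    attr(out, "skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 6L)) {
    stop("malformed SAM record in ", path, call. = FALSE)
  }
  flag <- as.integer(vapply(fields, `[[`, character(1), 2L))
  chrom <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4L))
  cigar <- vapply(fields, `[[`, character(1), 6L)

  mapped <- bitwAnd(flag, 4L) == 0L
  skipped <- skipped + sum(!mapped)
  no_cigar <- mapped & cigar == "*"
  if (any(no_cigar)) {
    warning(sum(no_cigar), " mapped record(s) with CIGAR '*' skipped")
    skipped <- skipped + sum(no_cigar)
  }
  keep <- mapped & cigar != "*"
  span <- vapply(cigar[keep], cigar_ref_span, integer(1), USE.NAMES = FALSE)
  out <- data.frame(chrom = chrom[keep],
                    start = pos[keep] - 1L,
                    end = pos[keep] - 1L + span,
                    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Write aligned reads as a minimal SAM file
#'
#' Emits @HD/@SQ headers and one minimal record per read (fixed-length match
#' CIGAR, `*` sequence). Used by the simulators so generated reads round-trip
#' through [read_alignments()].
#'
#' @param reads Data frame with `chrom`, `start`, `end`, `strand`.
#' @param seqlengths Named vector of chromosome lengths for the @SQ headers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (nrow(reads)) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    writeLines(sprintf("r%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       seq_len(nrow(reads)), flag, reads$chrom,
                       reads$start + 1L, reads$end - reads$start), con)
  }
  invisible(path)
}

#' Read a gene/TSS annotation table
#'
#' Tab-separated with header columns `gene`, `chrom`, `tss` (0-based bp),
#' `strand`, `class`; `class` must be one of `up`, `down`,
#' `unchanged_expressed`, `not_expressed`.
#'
#' @param path Input path.
#' @return A validated `data.frame`.
#' @export
read_gene_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- c("up", "down", "unchanged_expressed", "not_expressed")
  if (!all(df$class %in% ok)) {
    stop("gene classes must be in {", paste(ok, collapse = ", "), "}",
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be + or -", call. = FALSE)
  }
  df
}

## data.frame intervals (0-based half-open) <-> GRanges (1-based closed)
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
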