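#' Define a two-enzyme restriction scheme
#'
#' The first (primary) cutter defines the analysis fragment map; the second
#' cutter is only used to flag "blind" fragments, i.e. first-cutter fragments
#' without an internal secondary site, whose ends behave anomalously during
#' 4C library preparation.
#'
#' @param primary Recognition motif of the first cutter (default `"GATC"`,
#'   DpnII).
#' @param secondary Recognition motif of the second cutter (default `"GTAC"`,
#'   Csp6I).
#' @return An object of class `cutter_scheme`.
#' @details Motifs must be non-empty uppercase A/C/G/T strings. The defaults
#'   are their own reverse complements; a non-palindromic motif is scanned on
#'   both strands.
#' @export
#' @examples
#' cutter_scheme()
cutter_scheme <- function(primary = "GATC", secondary = "GTAC") {
  for (m in c(primary, secondary)) {
    if (!is.character(m) || length(m) != 1L || nchar(m) == 0L ||
        !grepl("^[ACGT]+$", m)) {
      stop("cutter motifs must be non-empty uppercase A/C/G/T strings, got '",
           m, "'", call. = FALSE)
    }
  }
  structure(list(primary = primary, secondary = secondary),
            class = "cutter_scheme")
}

#' @export
print.cutter_scheme <- function(x, ...) {
  cat("cutter_scheme: primary =", x$primary, "| secondary =", x$secondary, "\n")
  invisible(x)
}

## 0-based start positions of a motif on either strand of a sequence.
## Occurrences containing N never match (Biostrings fixed matching).
motif_positions <- function(seq, motif) {
  subject <- if (methods::is(seq, "DNAString")) seq else
    Biostrings::DNAString(toupper(as.character(seq)))
  pos <- Biostrings::start(Biostrings::matchPattern(motif, subject,
                                                    fixed = TRUE)) - 1L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  if (!identical(rc, motif)) {
    pos <- c(pos,
             Biostrings::start(Biostrings::matchPattern(rc, subject,
                                                        fixed = TRUE)) - 1L)
  }
  sort(unique(pos))
}

#' Virtually digest one sequence into an ordered fragment list
#'
#' Fragment boundaries are placed at the first base of each primary-site
#' occurrence (blunt model; overlapping occurrences allowed, duplicate
#' boundaries deduplicated). The first fragment starts at 0 and the last ends
#' at the sequence length, so fragments tile `[0, L)` contiguously. A cut at
#' position 0 coincides with the leading boundary and does not create an
#' empty fragment. Each fragment's `blind` flag is TRUE when no secondary-site
#' occurrence is fully contained in `[start, end)`.
#'
#' @param sequence A character string or `DNAString` over A/C/G/T/N
#'   (case-insensitive). Motif matches never span an N.
#' @param scheme A [cutter_scheme()].
#' @param chrom Optional chromosome name recorded in the result.
#' @return A `data.frame` with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `index` (0-based ordinal) and `blind`.
#'   A sequence without any primary site yields a single fragment `[0, L)`.
#' @export
#' @examples
#' digest("TTGATCTTTTTTGATCTT", cutter_scheme())
digest <- function(sequence, scheme = cutter_scheme(), chrom = "chr") {
  seq_chr <- toupper(as.character(sequence))
  if (length(seq_chr) != 1L || nchar(seq_chr) == 0L) {
    stop("empty chromosome", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq_chr)) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  subject <- Biostrings::DNAString(seq_chr)
  len <- length(subject)
  cuts <- motif_positions(subject, scheme$primary)
  bounds <- unique(c(0L, cuts, len))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]

  blind <- rep(TRUE, length(starts))
  sec <- motif_positions(subject, scheme$secondary)
  if (length(sec)) {
    sec_end <- sec + nchar(scheme$secondary)
    # fragment containing each secondary occurrence (full containment)
    idx <- findInterval(sec, starts)
    contained <- sec_end <= ends[idx]
    blind[unique(idx[contained])] <- FALSE
  }
  data.frame(chrom = chrom, start = starts, end = ends,
             index = seq_along(starts) - 1L, blind = blind,
             stringsAsFactors = FALSE)
}

#' Build a fragment map for a multi-chromosome reference
#'
#' @param genome A named character vector, a `DNAStringSet`, or a path to a
#'   FASTA file (headers tokenized at the first whitespace).
#' @param scheme A [cutter_scheme()].
#' @return A `FragmentMap`: list with `fragments` (named list of per-chromosome
#'   fragment data frames from [digest()]), `seqlengths`, and the `scheme`.
#' @export
fragment_map <- function(genome, scheme = cutter_scheme()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else if (is.character(genome)) {
    seqs <- genome
  } else {
    stop("genome must be a FASTA path, DNAStringSet or named character vector",
         call. = FALSE)
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("all chromosomes must be named", call. = FALSE)
  }
  frags <- lapply(names(seqs), function(ch) digest(seqs[[ch]], scheme, ch))
  names(frags) <- names(seqs)
  structure(list(fragments = frags,
                 seqlengths = vapply(seqs, nchar, integer(1)),
                 scheme = scheme),
            class = "FragmentMap")
}

#' @export
print.FragmentMap <- function(x, ...) {
  cat("FragmentMap:", length(x$fragments), "chromosome(s),",
      sum(vapply(x$fragments, nrow, integer(1))), "fragments",
      sprintf("(%s/%s)\n", x$scheme$primary, x$scheme$secondary))
  invisible(x)
}

#' Locate the fragment containing a position
#'
#' Binary-search lookup of the unique fragment with `start <= pos < end`.
#'
#' @param map A [fragment_map()].
#' @param chrom Chromosome name.
#' @param pos 0-based position.
#' @return A one-row fragment data frame.
#' @export
locate_fragment <- function(map, chrom, pos) {
  stopifnot(inherits(map, "FragmentMap"))
  frs <- map$fragments[[chrom]]
  if (is.null(frs)) {
    stop("chromosome '", chrom, "' not in fragment map", call. = FALSE)
  }
  if (length(pos) != 1L || is.na(pos) || pos < 0 ||
      pos >= map$seqlengths[[chrom]]) {
    stop("position ", pos, " out of range on ", chrom,
         " [0, ", map$seqlengths[[chrom]], ")", call. = FALSE)
  }
  i <- findInterval(pos, frs$start)
  frs[i, , drop = FALSE]
}

#' Write a fragment map as BED4
#'
#' One line per fragment, name `frag_<index>;blind=<0|1>`.
#'
#' @param map A [fragment_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_bed <- function(map, path) {
  stopifnot(inherits(map, "FragmentMap"))
  all <- do.call(rbind, map$fragments)
  bed <- data.frame(chrom = all$chrom, start = all$start, end = all$end,
                    name = sprintf("frag_%d;blind=%d", all$index,
                                   as.integer(all$blind)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
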