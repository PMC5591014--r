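#' Describe a 4C viewpoint
#'
#' @param name Viewpoint label (e.g. a promoter name).
#' @param chrom Chromosome.
#' @param position 0-based bp position inside the viewpoint fragment
#'   (typically the fragment midpoint).
#' @param map A [fragment_map()] used to resolve the viewpoint fragment.
#' @param exclusion_radius Number of fragments on each side of the viewpoint
#'   fragment masked from analysis (self-ligation and undigested artifacts).
#' @return A `ViewpointSpec` list with the resolved
#'   `viewpoint_fragment_index`.
#' @export
viewpoint_spec <- function(name, chrom, position, map, exclusion_radius = 2L) {
  stopifnot(exclusion_radius >= 0)
  frag <- locate_fragment(map, chrom, position)
  structure(list(name = name, chrom = chrom, position = position,
                 viewpoint_fragment_index = frag$index,
                 exclusion_radius_fragments = as.integer(exclusion_radius)),
            class = "ViewpointSpec")
}

#' Call captured fragment ends from aligned 4C reads
#'
#' A fragment end counts as captured (ligated to the viewpoint) when at least
#' one read maps exactly at the end, oriented toward the fragment center: the
#' left end of fragment `[s, e)` needs a `+` read with `start == s`, the
#' right end a `-` read with `end == e`. All other reads are ignored.
#' Capture is a presence call, so read duplication does not change it.
#'
#' @param reads Data frame with `chrom`, `start`, `end`, `strand` (e.g. from
#'   [read_alignments()]).
#' @param map A [fragment_map()].
#' @return A `capture_calls` object: per-chromosome data frames with `index`,
#'   `left`, `right` logical columns, plus counts of used/ignored/skipped
#'   reads in `log`.
#' @export
call_captured_ends <- function(reads, map) {
  stopifnot(inherits(map, "FragmentMap"))
  known <- reads$chrom %in% names(map$fragments)
  if (any(!known)) {
    warning(sum(!known), " read(s) on chromosomes absent from the fragment ",
            "map skipped")
  }
  reads <- reads[known, , drop = FALSE]
  used <- 0L
  calls <- lapply(names(map$fragments), function(ch) {
    frs <- map$fragments[[ch]]
    r <- reads[reads$chrom == ch, , drop = FALSE]
    left <- frs$start %in% r$start[r$strand == "+"]
    right <- frs$end %in% r$end[r$strand == "-"]
    # count reads that support some end call (diagnostic only)
    used <<- used + sum(r$strand == "+" & r$start %in% frs$start) +
      sum(r$strand == "-" & r$end %in% frs$end)
    data.frame(index = frs$index, left = left, right = right)
  })
  names(calls) <- names(map$fragments)
  structure(list(calls = calls,
                 log = c(reads_total = nrow(reads) + sum(!known),
                         reads_end_matching = used,
                         reads_ignored = nrow(reads) - used,
                         reads_skipped_unknown_chrom = sum(!known))),
            class = "capture_calls")
}

#' Summarize capture calls in sliding fragment windows
#'
#' Windows of `window_size` consecutive fragments (default 30, so at most 60
#' captured sites per window) slide along the viewpoint chromosome with the
#' given step. Each window records the captured-site count `c` over its
#' `2 * window_size` fragment ends, the frequency `f = c / (2 * window_size)`,
#' the genomic midpoint and its distance to the viewpoint. Windows containing
#' fragments inside the viewpoint exclusion zone are flagged `excluded`. A
#' chromosome shorter than one window yields a single truncated, excluded
#' window.
#'
#' @param calls A [call_captured_ends()] result.
#' @param map A [fragment_map()].
#' @param viewpoint A [viewpoint_spec()].
#' @param window_size Fragments per window.
#' @param step Window step in fragments.
#' @return A `CaptureProfile`: list with `viewpoint`, `replicate`, `windows`
#'   data frame (`window`, `frag_first`, `frag_last`, `chrom`, `start`,
#'   `end`, `midpoint`, `distance`, `side`, `c`, `f`, `excluded`,
#'   `truncated`).
#' @param replicate Replicate identifier stored in the profile.
#' @export
windowize <- function(calls, map, viewpoint, window_size = 30L, step = 1L,
                      replicate = "rep1") {
  stopifnot(inherits(calls, "capture_calls"), inherits(map, "FragmentMap"),
            inherits(viewpoint, "ViewpointSpec"),
            window_size >= 1L, step >= 1L)
  ch <- viewpoint$chrom
  frs <- map$fragments[[ch]]
  cc <- calls$calls[[ch]]
  if (is.null(frs) || is.null(cc)) {
    stop("viewpoint chromosome '", ch, "' absent from map or calls",
         call. = FALSE)
  }
  n <- nrow(frs)
  ends_per_frag <- as.integer(cc$left) + as.integer(cc$right)
  vp_idx <- viewpoint$viewpoint_fragment_index  # 0-based
  excl_lo <- vp_idx - viewpoint$exclusion_radius_fragments
  excl_hi <- vp_idx + viewpoint$exclusion_radius_fragments

  truncated <- n < window_size
  W <- min(window_size, n)
  first <- seq(1L, n - W + 1L, by = step)  # 1-based fragment row
  last <- first + W - 1L
  cs <- cumsum(ends_per_frag)
  cvals <- cs[last] - c(0L, cs)[first]
  start <- frs$start[first]
  end <- frs$end[last]
  mid <- (start + end) / 2
  dist <- abs(mid - viewpoint$position)
  # excluded if window's fragment index range intersects the exclusion zone
  idx_first <- frs$index[first]
  idx_last <- frs$index[last]
  excluded <- (idx_first <= excl_hi) & (idx_last >= excl_lo)
  if (truncated) excluded <- rep(TRUE, length(first))

  windows <- data.frame(
    window = seq_along(first),
    frag_first = idx_first, frag_last = idx_last,
    chrom = ch, start = start, end = end,
    midpoint = mid, distance = dist,
    side = ifelse(mid < viewpoint$position, "upstream", "downstream"),
    c = as.integer(cvals), f = cvals / (2 * W),
    excluded = excluded, truncated = truncated,
    stringsAsFactors = FALSE)
  structure(list(viewpoint = viewpoint, replicate = replicate,
                 window_size = W, step = step,
                 calls = calls, windows = windows),
            class = "CaptureProfile")
}

#' @export
print.CaptureProfile <- function(x, ...) {
  cat("CaptureProfile:", x$viewpoint$name, "replicate", x$replicate, "-",
      nrow(x$windows), "windows of", x$window_size, "fragments;",
      sum(x$windows$excluded), "excluded\n")
  invisible(x)
}

#' Build a capture profile from reads in one call
#'
#' Convenience composition of [call_captured_ends()] and [windowize()].
#'
#' @inheritParams windowize
#' @param reads Data frame of aligned reads.
#' @return A `CaptureProfile`.
#' @export
capture_profile <- function(reads, map, viewpoint, window_size = 30L,
                            step = 1L, replicate = "rep1") {
  windowize(call_captured_ends(reads, map), map, viewpoint,
            window_size = window_size, step = step, replicate = replicate)
}

#' Write a capture profile as TSV and bedGraph
#'
#' @param profile A `CaptureProfile`.
#' @param tsv_path Output TSV path (per-window `c`, `f`, distance, flags);
#'   `NULL` to skip.
#' @param bedgraph_path Output bedGraph path carrying `f`; `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_capture_profile <- function(profile, tsv_path = NULL,
                                  bedgraph_path = NULL) {
  w <- profile$windows
  if (!is.null(tsv_path)) {
    write.table(w, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bedgraph_path)) {
    write_bedgraph(data.frame(chrom = w$chrom, start = w$start, end = w$end,
                              score = w$f), bedgraph_path)
  }
  invisible(c(tsv = tsv_path, bedgraph = bedgraph_path))
}
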