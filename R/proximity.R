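#' Nearest TSS-to-feature distance
#'
#' For every gene, the unsigned distance from its TSS to the nearest feature
#' interval: 0 when the TSS lies inside an interval, otherwise the distance
#' to the nearest occupied base (`start` or `end - 1`). Genes on chromosomes
#' without any feature get `NA` with a message.
#'
#' @param genes Gene table (`gene`, `chrom`, `tss`, ...; see
#'   [read_gene_table()]).
#' @param features Interval data frame (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @return `genes` with an added `distance` column.
#' @export
nearest_distance <- function(genes, features) {
  if (nrow(features) == 0L) {
    genes$distance <- NA_real_
    message("feature set empty: all distances missing")
    return(genes)
  }
  q <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  s <- intervals_to_gr(features)
  d <- rep(NA_real_, nrow(genes))
  # suppress the benign seqlevel-mismatch warning when a gene's chromosome
  # carries no features
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, s, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  # distanceToNearest reports the gap (0 for overlap or adjacency); the
  # nearest occupied base is gap + 1 away unless the TSS overlaps a feature
  ov <- suppressWarnings(GenomicRanges::countOverlaps(q, s) > 0)
  d[qi] <- ifelse(ov[qi], 0, gap + 1)
  missing <- which(is.na(d))
  if (length(missing)) {
    message(length(missing), " gene(s) on chromosomes without features: ",
            "distance missing")
  }
  genes$distance <- d
  genes
}

#' Feature frequency in windows around the TSS, relative to unchanged genes
#'
#' For each expression class and window width `w`, `F` is the fraction of
#' genes with at least one feature overlapping `[TSS - w/2, TSS + w/2)`;
#' `RF = F_class / F_unchanged_expressed` expresses it relative to expressed
#' but unchanged genes. `w = 0` degenerates to counting features that
#' overlap the TSS base itself.
#'
#' @param genes Gene table with `class` column.
#' @param features Interval data frame.
#' @param windows Numeric vector of window widths in bp (default 10 kb and
#'   20 kb).
#' @return Data frame with `class`, `window`, `n_genes`, `F`, `RF`.
#' @export
window_frequency <- function(genes, features, windows = c(10000, 20000)) {
  if (!any(genes$class == "unchanged_expressed")) {
    stop("reference class 'unchanged_expressed' is empty", call. = FALSE)
  }
  s <- intervals_to_gr(features)
  res <- lapply(windows, function(w) {
    if (w == 0) {  # degenerate: the TSS base itself
      lo <- genes$tss
      hi <- genes$tss + 1L
    } else {
      lo <- genes$tss - floor(w / 2)
      hi <- genes$tss + ceiling(w / 2)
    }
    q <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(lo + 1L, hi))
    has <- suppressWarnings(GenomicRanges::countOverlaps(q, s) > 0)
    agg <- tapply(has, genes$class, mean)
    data.frame(class = names(agg), window = w,
               n_genes = as.integer(table(genes$class)[names(agg)]),
               F = as.numeric(agg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ref <- out$F[out$class == "unchanged_expressed"]
  names(ref) <- out$window[out$class == "unchanged_expressed"]
  out$RF <- out$F / ref[as.character(out$window)]
  if (any(ref == 0)) {
    warning("reference class frequency is 0 for some window(s); ",
            "RF reported as missing")
    out$RF[!is.finite(out$RF)] <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Permutation null for a gene-set statistic
#'
#' Draws `n_draws` gene sets of the observed size without replacement from
#' the expressed-gene pool, evaluates `statistic_fn` on each, and reports
#' add-one empirical p-values: upper tail
#' `p = (1 + #\{null >= observed\}) / (n_draws + 1)`, lower tail
#' analogously, two-sided `= min(1, 2 * min(upper, lower))`. The smallest
#' attainable p is `1 / (n_draws + 1)`.
#'
#' @param statistic_fn Deterministic function of a gene-table subset
#'   returning one number (e.g. mean nearest distance, or a window
#'   frequency).
#' @param class_genes Gene-table rows of the class under test.
#' @param expressed_pool Gene-table rows to draw null sets from; must be at
#'   least as large as `class_genes`.
#' @param n_draws Number of permutation draws (default 5000).
#' @param seed Integer seed (required; all randomness is explicit).
#' @param half_open Interpretation note: ties count toward the tail.
#' @return A `PermutationNull` list: `observed`, `null` values, `null_mean`,
#'   `null_sd`, `p_upper`, `p_lower`, `p_two_sided`, `n_draws`.
#' @export
permutation_null <- function(statistic_fn, class_genes, expressed_pool,
                             n_draws = 5000L, seed, half_open = TRUE) {
  k <- nrow(class_genes)
  n <- nrow(expressed_pool)
  if (n < k) {
    stop("expressed pool (", n, ") smaller than the gene class (", k, ")",
         call. = FALSE)
  }
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  observed <- statistic_fn(class_genes)
  null <- vapply(seq_len(n_draws), function(i) {
    statistic_fn(expressed_pool[sample.int(n, k), , drop = FALSE])
  }, numeric(1))
  p_up <- (1 + sum(null >= observed)) / (n_draws + 1)
  p_lo <- (1 + sum(null <= observed)) / (n_draws + 1)
  structure(list(observed = observed, null = null,
                 null_mean = mean(null), null_sd = sd(null),
                 p_upper = p_up, p_lower = p_lo,
                 p_two_sided = min(1, 2 * min(p_up, p_lo)),
                 n_draws = n_draws),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf(
    "PermutationNull: observed = %.4g, null = %.4g +/- %.4g (N = %d)\n",
    x$observed, x$null_mean, x$null_sd, x$n_draws))
  cat(sprintf("  p (upper/lower/two-sided) = %.4g / %.4g / %.4g\n",
              x$p_upper, x$p_lower, x$p_two_sided))
  invisible(x)
}

#' Mann-Whitney U test with exact small-sample branch
#'
#' The U statistic uses midranks for ties. When `length(x) + length(y) <= 14`
#' and there are no ties the p-value is exact (full enumeration of rank
#' assignments, via the exact Wilcoxon distribution); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `U` (for `x`), `p`, and the `method` branch used.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- (length(x) + length(y) <= 14L) && !anyDuplicated(c(x, y))
  ht <- wilcox.test(x, y, alternative = alternative, exact = exact,
                    correct = TRUE)
  list(U = unname(ht$statistic), p = unname(ht$p.value),
       method = if (exact) "exact" else "normal_approx")
}

#' Derive tissue-specific peaks by interval subtraction
#'
#' Merges the interval sets from the other tissues (union with overlapping
#' intervals coalesced) and keeps the focal intervals with zero overlap
#' (at the 1 bp level) with that union.
#'
#' @param focal Focal tissue's interval data frame.
#' @param others List of interval data frames from other tissues (may be
#'   empty, in which case the focal set is returned unchanged).
#' @return The tissue-specific subset of `focal`.
#' @export
tissue_specific_peaks <- function(focal, others) {
  if (length(others) == 0L) return(focal)
  merged <- GenomicRanges::reduce(
    do.call(c, lapply(others, intervals_to_gr)))
  keep <- GenomicRanges::countOverlaps(intervals_to_gr(focal), merged) == 0
  focal[keep, , drop = FALSE]
}

## moving average with shrinking windows at the edges
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- floor(width / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

## step-function lookup of a bedGraph track at given positions on one chrom;
## positions not covered return NA
track_values_at <- function(track_chr, pos) {
  if (nrow(track_chr) == 0L) return(rep(NA_real_, length(pos)))
  o <- order(track_chr$start)
  starts <- track_chr$start[o]
  ends <- track_chr$end[o]
  score <- track_chr$score[o]
  i <- findInterval(pos, starts)
  val <- rep(NA_real_, length(pos))
  ok <- i >= 1L
  ok[ok] <- pos[ok] < ends[i[ok]]
  val[ok] <- score[i[ok]]
  val
}

#' Signal meta-profile around the TSS by gene class
#'
#' Extracts a signal track in `[TSS - half_width, TSS + half_width)` at a
#' fixed bin width for every gene (sampled at bin centers of the bedGraph
#' step function; uncovered positions count as 0 and are tallied).
#' Minus-strand genes are flipped so that downstream of the TSS is positive.
#' Values are z-scored per chromosome (subtracting that chromosome's mean
#' over all extracted values and dividing by its SD), averaged within each
#' class per bin, and smoothed with a centered moving average.
#'
#' @param genes Gene table (`chrom`, `tss`, `strand`, `class`).
#' @param track Signal data frame (`chrom`, `start`, `end`, `score`), e.g.
#'   from [read_bedgraph()].
#' @param half_width Half-width of the extraction window in bp (default
#'   2000).
#' @param bin_width Bin width in bp (default 10).
#' @param smooth_bins Width of the centered moving average (default 5).
#' @return A `MetaProfile` list: `position` (bin centers relative to the
#'   TSS), `values` (gene x bin matrix, strand-flipped), `zvalues`
#'   (per-chromosome z-scored), `profiles` data frame (`class`, `position`,
#'   `mean_z`, `smoothed`), and `n_missing` uncovered positions.
#' @export
meta_profile <- function(genes, track, half_width = 2000L, bin_width = 10L,
                         smooth_bins = 5L) {
  stopifnot(half_width %% bin_width == 0)
  nb <- as.integer(2 * half_width / bin_width)
  rel <- -half_width + (seq_len(nb) - 1) * bin_width + bin_width / 2
  empty_classes <- setdiff(unique(genes$class), genes$class)
  n_missing <- 0L
  vals <- matrix(NA_real_, nrow(genes), nb)
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    pos <- as.vector(outer(rel, genes$tss[gi], `+`))  # bin centers per gene
    v <- track_values_at(tr, pos)
    n_missing <- n_missing + sum(is.na(v))
    v[is.na(v)] <- 0
    vals[gi, ] <- matrix(v, ncol = nb, byrow = TRUE)
  }
  flip <- genes$strand == "-"
  vals[flip, ] <- vals[flip, rev(seq_len(nb)), drop = FALSE]
  if (n_missing > 0) {
    message(n_missing, " extracted position(s) not covered by the track; ",
            "treated as 0")
  }
  zvals <- vals
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    m <- mean(vals[gi, ])
    s <- sd(as.vector(vals[gi, ]))
    zvals[gi, ] <- if (is.na(s) || s == 0) 0 else (vals[gi, ] - m) / s
  }
  profiles <- do.call(rbind, lapply(unique(genes$class), function(cl) {
    gi <- which(genes$class == cl)
    if (!length(gi)) {
      warning("class '", cl, "' has no genes; empty profile")
      return(NULL)
    }
    mz <- colMeans(zvals[gi, , drop = FALSE])
    data.frame(class = cl, position = rel, mean_z = mz,
               smoothed = moving_average(mz, smooth_bins),
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  structure(list(position = rel, values = vals, zvalues = zvals,
                 profiles = profiles, n_missing = n_missing,
                 bin_width = bin_width, half_width = half_width),
            class = "MetaProfile")
}
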