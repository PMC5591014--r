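#' Normalize capture profiles by regional total signal
#'
#' Every sample is rescaled so that its summed window count over a
#' normalization region centered on the viewpoint (default span 15 Mb, i.e.
#' viewpoint +/- 7.5 Mb) equals the across-sample mean of the raw regional
#' totals. Relative per-window proportions within a sample are unchanged and
#' the operation is idempotent.
#'
#' @param profiles Named list of [capture_profile()] results on identical
#'   window grids (names are sample ids).
#' @param span_bp Width of the normalization region in bp (default
#'   15,000,000).
#' @return A `NormalizedProfileSet`: list with the window `grid`, `raw` and
#'   `normalized` count matrices (windows x samples), `scale_factors`, and
#'   the `region` bounds.
#' @export
normalize_regional <- function(profiles, span_bp = 15e6) {
  stopifnot(length(profiles) >= 1L)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("sample", seq_along(profiles))
  }
  grids <- lapply(profiles, function(p) p$windows[, c("chrom", "start", "end")])
  for (g in grids[-1]) {
    if (!identical(g, grids[[1]])) {
      stop("profiles have mismatched window grids", call. = FALSE)
    }
  }
  vp <- profiles[[1]]$viewpoint
  region <- c(lo = vp$position - span_bp / 2, hi = vp$position + span_bp / 2)
  grid <- profiles[[1]]$windows[, c("window", "chrom", "start", "end",
                                    "midpoint", "distance", "excluded")]
  in_region <- grid$chrom == vp$chrom &
    grid$midpoint >= region[["lo"]] & grid$midpoint <= region[["hi"]]
  if (!any(in_region)) {
    stop("normalization region overlaps no windows", call. = FALSE)
  }
  raw <- vapply(profiles, function(p) as.numeric(p$windows$c),
                numeric(nrow(grid)))
  totals <- colSums(raw[in_region, , drop = FALSE])
  if (any(totals == 0)) {
    stop("zero regional total for sample(s): ",
         paste(names(profiles)[totals == 0], collapse = ", "), call. = FALSE)
  }
  target <- mean(totals)
  sf <- target / totals
  normalized <- sweep(raw, 2, sf, `*`)
  structure(list(grid = grid, raw = raw, normalized = normalized,
                 scale_factors = sf, region = region, in_region = in_region),
            class = "NormalizedProfileSet")
}

#' Per-window group means, SDs and mean difference
#'
#' For each window, the sample mean and sample standard deviation (n - 1
#' denominator) of the normalized signal are computed within each condition;
#' `delta` is the mean of the first condition level minus the mean of the
#' second, so swapping the labels negates it. With a single replicate the SD
#' is reported as `NA`.
#'
#' @param nps A [normalize_regional()] result.
#' @param conditions Factor (or vector) of length `ncol(normalized)` with
#'   exactly two levels assigning samples to conditions.
#' @return A `GroupContrast` data frame with per-window `mean_<A>`, `sd_<A>`,
#'   `mean_<B>`, `sd_<B>` and `delta`.
#' @export
group_stats <- function(nps, conditions) {
  stopifnot(inherits(nps, "NormalizedProfileSet"))
  conditions <- as.factor(conditions)
  if (length(conditions) != ncol(nps$normalized) ||
      nlevels(conditions) != 2L) {
    stop("conditions must assign every sample to one of exactly two levels",
         call. = FALSE)
  }
  lv <- levels(conditions)
  out <- nps$grid
  for (l in lv) {
    m <- nps$normalized[, conditions == l, drop = FALSE]
    out[[paste0("mean_", l)]] <- rowMeans(m)
    out[[paste0("sd_", l)]] <-
      if (ncol(m) >= 2L) apply(m, 1, sd) else NA_real_
  }
  out$delta <- out[[paste0("mean_", lv[1])]] - out[[paste0("mean_", lv[2])]]
  structure(out, conditions = lv,
            class = c("GroupContrast", "data.frame"))
}

#' Exact conditional count test between two conditions
#'
#' For each unit (window), conditioning on the total raw count across all
#' samples, the summed count of the first condition is binomial under the
#' null with success probability equal to the first condition's share of the
#' effective library size. The two-sided p-value sums the probabilities of
#' all outcomes no more probable than the observed one. A method-of-moments
#' common dispersion across units is estimated from library-size-scaled
#' counts and attached as a diagnostic (`attr(, "dispersion")`); the test
#' itself assumes dispersion 0 — a documented limitation for strongly
#' overdispersed replicates.
#'
#' @param counts Integer matrix of raw counts (units x samples).
#' @param conditions Two-level factor/vector over samples.
#' @param lib_sizes Effective library sizes per sample; defaults to the
#'   column sums of `counts`.
#' @return Data frame with per-unit condition sums, `p` and BH-adjusted `q`;
#'   attribute `dispersion` holds the moment estimate.
#' @export
nb_test <- function(counts, conditions, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("nb_test requires non-negative integer raw counts ",
         "(apply it before normalization)", call. = FALSE)
  }
  conditions <- as.factor(conditions)
  if (length(conditions) != ncol(counts) || nlevels(conditions) != 2L) {
    stop("conditions must assign every sample to one of exactly two levels",
         call. = FALSE)
  }
  lv <- levels(conditions)
  a <- conditions == lv[1]
  xa <- rowSums(counts[, a, drop = FALSE])
  xb <- rowSums(counts[, !a, drop = FALSE])
  pi_a <- sum(lib_sizes[a]) / sum(lib_sizes)
  p <- vapply(seq_along(xa), function(i) {
    tot <- xa[i] + xb[i]
    if (tot == 0) return(1)
    pr <- dbinom(0:tot, tot, pi_a)
    sum(pr[pr <= pr[xa[i] + 1] * (1 + 1e-9)])
  }, numeric(1))
  p <- pmin(p, 1)

  # moment-based common dispersion on library-scaled counts (diagnostic)
  scl <- sweep(counts, 2, mean(lib_sizes) / lib_sizes, `*`)
  mu <- rowMeans(scl)
  if (ncol(counts) >= 3L) {
    v <- apply(scl, 1, var)
    ok <- mu > 0
    disp <- if (any(ok)) {
      max(0, median((v[ok] - mu[ok]) / mu[ok]^2))
    } else NA_real_
  } else {
    disp <- NA_real_
  }
  out <- data.frame(unit = seq_along(xa),
                    count_a = xa, count_b = xb,
                    p = p, q = bh_adjust(p))
  names(out)[2:3] <- paste0("count_", lv)
  structure(out, dispersion = disp, conditions = lv)
}

#' Compare two conditions across replicated 4C profiles
#'
#' Composition of [normalize_regional()], [group_stats()] and [nb_test()]
#' (the count test runs on raw, pre-normalization window counts with the
#' regional totals as effective library sizes).
#'
#' @param profiles Named list of `CaptureProfile`s.
#' @param conditions Two-level factor over the profiles.
#' @param span_bp Normalization region width in bp.
#' @return A data frame joining the group contrast with the test's `p`/`q`;
#'   attributes `scale_factors` and `dispersion`.
#' @export
differential_contacts <- function(profiles, conditions, span_bp = 15e6) {
  nps <- normalize_regional(profiles, span_bp = span_bp)
  gs <- group_stats(nps, conditions)
  raw <- round(nps$raw)
  lib <- colSums(nps$raw[nps$in_region, , drop = FALSE])
  nt <- nb_test(raw, conditions, lib_sizes = lib)
  gs$p <- nt$p
  gs$q <- nt$q
  structure(gs, scale_factors = nps$scale_factors,
            dispersion = attr(nt, "dispersion"),
            class = c("GroupContrast", "data.frame"))
}
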