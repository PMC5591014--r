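## Pool-adjacent-violators for a non-increasing least-squares fit with
## uniform weights. Classic block-merging algorithm; O(n).
pava_nonincreasing <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  # fit non-decreasing to the reversed series, then reverse back
  yy <- rev(y)
  ww <- rev(w)
  val <- numeric(n)   # block means
  wt <- numeric(n)    # block weights
  len <- integer(n)   # block lengths
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- yy[i]; wt[k] <- ww[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      # merge violating adjacent blocks
      w2 <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / w2
      wt[k - 1L] <- w2
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rev(rep.int(val[seq_len(k)], len[seq_len(k)]))
}

#' Fit a monotone distance-decay model to a capture profile
#'
#' On each side of the viewpoint, the capture frequency `f` of non-excluded
#' windows is fitted against distance rank by isotonic (non-increasing)
#' least squares, solved with the pool-adjacent-violators algorithm. The
#' residuals `r = f - yhat` are standardized by a robust scale
#' `sigma = 1.4826 * mad(r)` (floored at 1e-6) into z-scores; one-sided
#' upper-tail p-values `p = 1 - pnorm(z)` test for enrichment above the
#' decay, and Benjamini-Hochberg adjustment is applied across all
#' non-excluded windows of the profile (both sides jointly).
#'
#' @param profile A [capture_profile()] result.
#' @param min_windows Minimum non-excluded windows required per side.
#' @return A `DecayFit` data frame: the non-excluded windows with added
#'   `rank`, `yhat`, `resid`, `z`, `p`, `q` columns; attribute `sigma` holds
#'   the per-side robust scales and `replicate` the profile's replicate id.
#' @export
fit_decay <- function(profile, min_windows = 5L) {
  stopifnot(inherits(profile, "CaptureProfile"))
  w <- profile$windows
  w <- w[!w$excluded & is.finite(w$distance), , drop = FALSE]
  sigmas <- c(upstream = NA_real_, downstream = NA_real_)
  pieces <- lapply(c("upstream", "downstream"), function(s) {
    ws <- w[w$side == s, , drop = FALSE]
    if (nrow(ws) < min_windows) {
      stop("insufficient windows for decay fit (", s, ": ", nrow(ws),
           " < ", min_windows, ")", call. = FALSE)
    }
    ws <- ws[order(ws$distance), , drop = FALSE]
    ws$rank <- seq_len(nrow(ws))
    ws$yhat <- pava_nonincreasing(ws$f)
    ws$resid <- ws$f - ws$yhat
    if (all(ws$f == 0)) {
      warning("all capture frequencies zero on ", s,
              " side; z-scores set to 0")
      sigma <- 1e-6
      ws$z <- 0
    } else {
      sigma <- max(1.4826 * median(abs(ws$resid - median(ws$resid))), 1e-6)
      ws$z <- ws$resid / sigma
    }
    sigmas[[s]] <<- sigma
    ws
  })
  fit <- do.call(rbind, pieces)
  fit <- fit[order(fit$window), , drop = FALSE]
  fit$p <- pmax(pnorm(fit$z, lower.tail = FALSE), .Machine$double.xmin)
  fit$q <- bh_adjust(fit$p)
  rownames(fit) <- NULL
  structure(fit, sigma = sigmas, replicate = profile$replicate,
            class = c("DecayFit", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1 and returned in the
#' input order. A validated front-end to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted q-values in the input order; empty input gives empty
#'   output.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Call replicate-consensus significant contacts
#'
#' A window is a consensus significant contact when its z-score exceeds
#' `z_threshold` in every replicate and its BH-adjusted p-value is below
#' `q_threshold` in at least one replicate.
#'
#' @param fits List of two or more [fit_decay()] results on identical window
#'   grids.
#' @param z_threshold z-score cutoff applied to all replicates (default 2).
#' @param q_threshold Adjusted-p cutoff required in at least one replicate
#'   (default 0.05).
#' @return A `ContactCallSet` data frame: window coordinates, per-replicate
#'   `z_*` and `q_*` columns, and `consensus_significant`.
#' @export
score_contacts <- function(fits, z_threshold = 2, q_threshold = 0.05) {
  if (length(fits) < 2L) {
    stop("consensus rule requires >=2 replicates", call. = FALSE)
  }
  grid <- fits[[1]][, c("chrom", "start", "end", "window")]
  for (f in fits[-1]) {
    if (nrow(f) != nrow(grid) ||
        !identical(f[, c("chrom", "start", "end", "window")], grid)) {
      stop("mismatched window grids across replicates", call. = FALSE)
    }
  }
  reps <- vapply(seq_along(fits), function(i) {
    r <- attr(fits[[i]], "replicate")
    if (is.null(r)) paste0("rep", i) else as.character(r)
  }, character(1))
  out <- cbind(grid,
               frag_first = fits[[1]]$frag_first,
               frag_last = fits[[1]]$frag_last,
               distance = fits[[1]]$distance,
               f_mean = rowMeans(vapply(fits, `[[`,
                                        numeric(nrow(grid)), "f")))
  zmat <- vapply(fits, `[[`, numeric(nrow(grid)), "z")
  qmat <- vapply(fits, `[[`, numeric(nrow(grid)), "q")
  if (is.null(dim(zmat))) {
    zmat <- matrix(zmat, nrow = 1); qmat <- matrix(qmat, nrow = 1)
  }
  colnames(zmat) <- paste0("z_", reps)
  colnames(qmat) <- paste0("q_", reps)
  out <- cbind(out, zmat, qmat)
  out$consensus_significant <-
    rowSums(zmat > z_threshold) == length(fits) &
    rowSums(qmat < q_threshold) >= 1L
  structure(out, replicates = reps,
            z_threshold = z_threshold, q_threshold = q_threshold,
            class = c("ContactCallSet", "data.frame"))
}

#' Write consensus contacts as BED with z-scores
#'
#' Significant windows only; the score column carries the mean z across
#' replicates.
#'
#' @param calls A [score_contacts()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts_bed <- function(calls, path) {
  sig <- calls[calls$consensus_significant, , drop = FALSE]
  zcols <- grep("^z_", names(sig))
  bed <- data.frame(chrom = sig$chrom, start = sig$start, end = sig$end,
                    name = sprintf("contact_%d", sig$window),
                    score = round(rowMeans(sig[, zcols, drop = FALSE]), 3))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Estimate the power-law decay exponent from window counts
#'
#' Diagnostic estimate of `alpha` under `f(d) ~ A * d^(-alpha)`: a log-link
#' quasi-Poisson regression of the windowed captured-site count on log
#' distance, over non-excluded unsaturated windows (`f < f_max`, which also
#' drops the capped region next to the viewpoint). Unlike a log-log
#' least-squares fit this keeps empty far windows, avoiding censoring bias.
#'
#' @param windows A `CaptureProfile` or its `windows` data frame.
#' @param f_max Saturation cutoff; windows at or above it are excluded.
#' @return The estimated exponent (positive for decreasing decay).
#' @export
estimate_decay_exponent <- function(windows, f_max = 0.45) {
  if (inherits(windows, "CaptureProfile")) windows <- windows$windows
  w <- windows[!windows$excluded & windows$distance > 0 &
                 windows$f < f_max, , drop = FALSE]
  if (nrow(w) < 5L) {
    stop("insufficient windows for exponent estimate", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(c ~ log(distance), family = stats::quasipoisson(), data = w))
  -unname(stats::coef(fit)[2])
}
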