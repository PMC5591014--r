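## Named substream seed derived from a top-level seed: each generator draws
## from its own stream so components can be regenerated independently.
## Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  (as.numeric(seed) * 48271 + h * 7919) %% 2147483629
}

## Mutate one base inside every motif occurrence until neither motif occurs;
## gives a background with exactly zero cutter sites before injection.
scrub_motifs <- function(chars, motifs) {
  repeat {
    seq1 <- paste(chars, collapse = "")
    pos <- integer(0)
    for (m in motifs) pos <- c(pos, motif_positions(seq1, m))
    if (!length(pos)) return(chars)
    at <- pos + 1L  # mutate the first base of each occurrence
    cur <- chars[at]
    repl <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                           1), character(1))
    chars[at] <- repl
  }
}

#' Generate a random genome with controlled cutter-site density
#'
#' Builds a random A/C/G/T background free of both cutter motifs (chance
#' occurrences are disrupted), then injects primary and secondary sites as
#' independent Poisson processes at the stated per-bp rates. Realized site
#' counts are therefore Poisson around `rate * length`. Fully reproducible
#' from the seed.
#'
#' @param seed Integer seed.
#' @param length Chromosome length in bp (>= 1000).
#' @param gatc_rate,gtac_rate Per-bp injection rates of the primary and
#'   secondary sites, in `[0, 0.05)`. A rate of 0 injects no site, so
#'   digestion yields a single fragment.
#' @param chrom Chromosome name.
#' @param scheme A [cutter_scheme()].
#' @return Named character vector of length 1 (the sequence); attribute
#'   `site_counts` records the realized injected site counts.
#' @export
make_genome <- function(seed, length = 5e5, gatc_rate = 0.004,
                        gtac_rate = 0.004, chrom = "chrS",
                        scheme = cutter_scheme()) {
  if (length < 1000) stop("genome length must be >= 1 kb", call. = FALSE)
  if (gatc_rate < 0 || gatc_rate >= 0.05 || gtac_rate < 0 ||
      gtac_rate >= 0.05) {
    stop("cutter rates must lie in [0, 0.05)", call. = FALSE)
  }
  set.seed(as.integer(derive_seed(seed, "genome")))
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  chars <- scrub_motifs(chars, c(scheme$primary, scheme$secondary))

  # joint non-overlapping placement so a secondary site never overwrites a
  # primary one (and vice versa); neither motif can arise across a junction
  n1 <- rpois(1, gatc_rate * length)
  n2 <- rpois(1, gtac_rate * length)
  k <- max(nchar(scheme$primary), nchar(scheme$secondary))
  counts <- c(primary = 0L, secondary = 0L)
  if (n1 + n2 > 0) {
    slots <- sort(sample.int(length - 2L * k, n1 + n2)) + k
    keep <- c(TRUE, diff(slots) >= k)
    slots <- slots[keep]
    which_primary <- seq_along(slots) %in%
      sample.int(length(slots), round(length(slots) * n1 / (n1 + n2)))
    for (i in seq_along(slots)) {
      m <- if (which_primary[i]) scheme$primary else scheme$secondary
      chars[slots[i]:(slots[i] + nchar(m) - 1L)] <- strsplit(m, "")[[1]]
    }
    counts <- c(primary = sum(which_primary),
                secondary = sum(!which_primary))
  }
  out <- stats::setNames(paste(chars, collapse = ""), chrom)
  attr(out, "site_counts") <- counts
  out
}

## Per-end capture probability under power-law decay
## P(d) = min(cap, amplitude * (max(d, d_floor)/d_ref)^(-alpha))
decay_probability <- function(d, alpha, amplitude, d_ref = 10000,
                              d_floor = 1000, cap = 0.9) {
  pmin(cap, amplitude * (pmax(d, d_floor) / d_ref)^(-alpha))
}

#' Simulate 4C reads for one viewpoint and replicate set
#'
#' Each fragment end on the viewpoint chromosome is captured with probability
#' following a power-law distance decay `P(d) = A * (d / d_ref)^(-alpha)`
#' (floored near the viewpoint, capped at 0.9; 0.95 under enrichment).
#' Planted enriched fragment ranges multiply the capture probability by their
#' fold factor for the given condition. Every captured end emits at least one
#' read at the exact end position with the inward orientation (`+` at the
#' fragment start, `-` ending at the fragment end); extra reads per captured
#' end are negative-binomial. A configurable fraction of noise reads is
#' placed strictly away from fragment ends in either orientation, so correct
#' capture calling must ignore them.
#'
#' @param map A [fragment_map()].
#' @param viewpoint A [viewpoint_spec()].
#' @param seed Integer seed (one substream per replicate).
#' @param alpha Decay exponent (> 0; default 1).
#' @param amplitude Decay amplitude: nominal capture probability at
#'   `d_ref` = 10 kb before the 0.9 cap (default 1, i.e. capture is
#'   near-saturated out to about 10 kb from the viewpoint).
#' @param replicates Number of replicates to simulate (default 2).
#' @param enriched `NULL`, or a data frame with `frag_first`, `frag_last`
#'   (0-based fragment index range) and `fold` (> 1) for planted contacts.
#' @param noise_fraction Noise reads as a fraction of true reads (default
#'   0.1).
#' @param read_length Nominal read length in bp (default 36; shortened on
#'   small fragments).
#' @param mu_extra,dispersion Negative-binomial mean/dispersion of extra
#'   reads per captured end beyond the first (defaults 2 and 0.5).
#' @param condition Condition label recorded in the truth.
#' @return A list of per-replicate read data frames (`chrom`, `start`,
#'   `end`, `strand`), with attribute `truth` (a `SyntheticTruth` list:
#'   planted parameters, per-end capture probabilities, seeds).
#' @export
simulate_4c <- function(map, viewpoint, seed, alpha = 1, amplitude = 1,
                        replicates = 2L, enriched = NULL,
                        noise_fraction = 0.1, read_length = 36L,
                        mu_extra = 2, dispersion = 0.5,
                        condition = "control") {
  stopifnot(alpha > 0, inherits(viewpoint, "ViewpointSpec"))
  frs <- map$fragments[[viewpoint$chrom]]
  if (is.null(frs)) stop("viewpoint chromosome not in map", call. = FALSE)
  n <- nrow(frs)
  # end positions and distances: left ends at start, right ends at end
  end_pos <- c(frs$start, frs$end)
  end_side <- rep(c("left", "right"), each = n)
  d <- abs(end_pos - viewpoint$position)
  p <- decay_probability(d, alpha, amplitude)
  if (!is.null(enriched) && nrow(enriched)) {
    stopifnot(all(enriched$fold > 1))
    for (i in seq_len(nrow(enriched))) {
      in_rng <- rep(frs$index >= enriched$frag_first[i] &
                      frs$index <= enriched$frag_last[i], 2)
      p[in_rng] <- pmin(0.95, p[in_rng] * enriched$fold[i])
    }
  }
  reads <- lapply(seq_len(replicates), function(r) {
    set.seed(as.integer(derive_seed(seed, paste0("reads_", condition, "_", r))))
    captured <- rbinom(length(p), 1, p) == 1
    idx <- which(captured)           # index into the 2n ends
    fi <- ((idx - 1L) %% n) + 1L     # fragment row
    left <- idx <= n
    width <- frs$end[fi] - frs$start[fi]
    len <- pmin(read_length, width)
    nreads <- 1L + rnbinom(length(idx), mu = mu_extra, size = 1 / dispersion)
    rep_fi <- rep(fi, nreads)
    rep_left <- rep(left, nreads)
    rep_len <- rep(len, nreads)
    start <- ifelse(rep_left, frs$start[rep_fi],
                    frs$end[rep_fi] - rep_len)
    end <- ifelse(rep_left, frs$start[rep_fi] + rep_len, frs$end[rep_fi])
    strand <- ifelse(rep_left, "+", "-")
    df <- data.frame(chrom = viewpoint$chrom, start = start, end = end,
                     strand = strand, stringsAsFactors = FALSE)
    # noise reads strictly off the capture-defining positions
    n_noise <- round(noise_fraction * nrow(df))
    all_width <- frs$end - frs$start
    wide <- which(all_width >= read_length + 2L)
    if (n_noise > 0 && length(wide)) {
      nf <- wide[sample.int(length(wide), n_noise, replace = TRUE)]
      off <- vapply(nf, function(j) {
        sample.int(frs$end[j] - frs$start[j] - read_length - 1L, 1)
      }, integer(1))
      nstart <- frs$start[nf] + off  # > start, end < fragment end
      nstrand <- sample(c("+", "-"), n_noise, replace = TRUE)
      df <- rbind(df, data.frame(chrom = viewpoint$chrom, start = nstart,
                                 end = nstart + read_length,
                                 strand = nstrand, stringsAsFactors = FALSE))
    }
    df[order(df$start), , drop = FALSE]
  })
  names(reads) <- paste0("rep", seq_len(replicates))
  truth <- list(seed = seed, alpha = alpha, amplitude = amplitude,
                condition = condition, enriched = enriched,
                noise_fraction = noise_fraction,
                capture_prob = p, end_pos = end_pos, end_side = end_side)
  attr(reads, "truth") <- truth
  reads
}

#' Generate a gene/feature fixture with planted proximity effects
#'
#' Genes of four expression classes are placed on two synthetic chromosomes.
#' Each gene's nearest "CTCF peak" and "enhancer" distances are drawn from
#' exponential distributions whose scale depends on the class: relative to
#' the unchanged-expressed scale `s`, a class with effect `k > 1` sits
#' `k`-fold closer (scale `s / k`). Defaults plant CTCF proximity for both
#' up- and downregulated genes but enhancer proximity only for downregulated
#' ones. A signal track of Gaussian bumps at CTCF peak centers on top of a
#' per-chromosome baseline covers +/- 3 kb of every TSS.
#'
#' @param seed Integer seed.
#' @param n_per_class Genes per class (>= 10).
#' @param scale_bp Exponential scale `s` of the unchanged-class distance
#'   (default 20 kb).
#' @param ctcf_effect Named effects (fold closer) for CTCF distances,
#'   defaults `c(up = 3, down = 3)`.
#' @param enhancer_effect Named effects for enhancer distances, default
#'   `c(down = 4)`.
#' @param chrom_length Length of each of the two chromosomes (default 10
#'   Mb).
#' @param peak_width Feature width in bp (default 200).
#' @return List with `genes` (gene table), `ctcf_peaks` and `enhancers`
#'   (interval data frames), `track` (signal data frame), and `truth`
#'   (planted parameters).
#' @export
make_gene_fixture <- function(seed, n_per_class = 200L, scale_bp = 20000,
                              ctcf_effect = c(up = 3, down = 3),
                              enhancer_effect = c(down = 4),
                              chrom_length = 1e7, peak_width = 200L) {
  if (n_per_class < 10L) stop("n_per_class must be >= 10", call. = FALSE)
  classes <- c("up", "down", "unchanged_expressed", "not_expressed")
  set.seed(as.integer(derive_seed(seed, "genes")))
  n <- n_per_class * length(classes)
  chroms <- c("chrA", "chrB")
  genes <- data.frame(
    gene = sprintf("g%04d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    tss = as.integer(runif(n, 1e5, chrom_length - 1e5)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    class = rep(classes, each = n_per_class),
    stringsAsFactors = FALSE)

  draw_features <- function(effects, stream) {
    set.seed(as.integer(derive_seed(seed, stream)))
    k <- rep(1, n)
    for (cl in names(effects)) k[genes$class == cl] <- effects[[cl]]
    dist <- rexp(n, rate = k / scale_bp)
    side <- sample(c(-1, 1), n, replace = TRUE)
    center <- pmax(peak_width,
                   pmin(chrom_length - peak_width,
                        genes$tss + side * (dist + peak_width / 2)))
    df <- data.frame(chrom = genes$chrom,
                     start = as.integer(round(center - peak_width / 2)),
                     end = as.integer(round(center + peak_width / 2)),
                     stringsAsFactors = FALSE)
    df[order(df$chrom, df$start), , drop = FALSE]
  }
  ctcf <- draw_features(ctcf_effect, "ctcf")
  enh <- draw_features(enhancer_effect, "enhancer")

  # signal: Gaussian bumps at CTCF centers + per-chromosome baseline,
  # tiled in 50 bp steps over +/- 3 kb of every TSS
  set.seed(as.integer(derive_seed(seed, "track")))
  baseline <- stats::setNames(c(0, 5), chroms)
  track <- do.call(rbind, lapply(chroms, function(ch) {
    g <- genes[genes$chrom == ch, ]
    if (!nrow(g)) return(NULL)
    grid <- sort(unique(unlist(lapply(g$tss, function(t) {
      seq(t - 3000, t + 3000, by = 50)
    }))))
    centers <- (ctcf$start[ctcf$chrom == ch] +
                  ctcf$end[ctcf$chrom == ch]) / 2
    sig <- rep(baseline[[ch]], length(grid))
    for (cc in centers) {
      near <- which(abs(grid - cc) < 1000)
      sig[near] <- sig[near] + exp(-((grid[near] - cc)^2) / (2 * 150^2))
    }
    data.frame(chrom = ch, start = grid, end = grid + 50L, score = sig,
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, ctcf_peaks = ctcf, enhancers = enh, track = track,
       truth = list(seed = seed, n_per_class = n_per_class,
                    scale_bp = scale_bp, ctcf_effect = ctcf_effect,
                    enhancer_effect = enhancer_effect,
                    baseline = baseline))
}

#' Write a synthetic fixture to disk with a truth manifest
#'
#' Emits `genes.tsv`, `ctcf_peaks.bed`, `enhancers.bed`, `signal.bedGraph`
#' and a plain-text `manifest.txt` (key=value truth parameters). Regeneration
#' from the same seed is byte-identical.
#'
#' @param fixture A [make_gene_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_gene_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(fixture$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_intervals(fixture$ctcf_peaks, file.path(dir, "ctcf_peaks.bed"))
  write_intervals(fixture$enhancers, file.path(dir, "enhancers.bed"))
  write_bedgraph(fixture$track, file.path(dir, "signal.bedGraph"))
  tr <- fixture$truth
  kv <- c(sprintf("seed=%d", tr$seed),
          sprintf("n_per_class=%d", tr$n_per_class),
          sprintf("scale_bp=%g", tr$scale_bp),
          sprintf("ctcf_effect_%s=%g", names(tr$ctcf_effect),
                  tr$ctcf_effect),
          sprintf("enhancer_effect_%s=%g", names(tr$enhancer_effect),
                  tr$enhancer_effect),
          sprintf("baseline_%s=%g", names(tr$baseline), tr$baseline))
  writeLines(kv, file.path(dir, "manifest.txt"))
  invisible(dir)
}
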