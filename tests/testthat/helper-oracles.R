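# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# 0-based cut positions by overlapping regex scan on both strands
oracle_cut_positions <- function(seq, motif) {
  seq <- toupper(seq)
  revcomp <- function(m) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(m, "")[[1]]), collapse = ""))
  }
  pos <- integer(0)
  for (m in unique(c(motif, revcomp(motif)))) {
    hits <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1]]
    if (hits[1] != -1) pos <- c(pos, as.integer(hits) - 1L)
  }
  sort(unique(pos))
}

# fragment table from cut positions (boundary at first base of occurrence)
oracle_digest <- function(seq, primary = "GATC", secondary = "GTAC") {
  L <- nchar(seq)
  bounds <- unique(c(0L, oracle_cut_positions(seq, primary), L))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  sec <- oracle_cut_positions(seq, secondary)
  blind <- vapply(seq_along(starts), function(i) {
    !any(sec >= starts[i] & sec + nchar(secondary) <= ends[i])
  }, logical(1))
  data.frame(start = starts, end = ends, blind = blind)
}

# random A/C/G/T sequence
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# non-increasing least-squares fit by exhaustive level-set enumeration
# (all 2^(n-1) partitions into contiguous blocks); n <= 12
oracle_isotonic_decreasing <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)  # block boundaries
    bounds <- c(0, cuts, n)
    means <- vapply(seq_len(length(bounds) - 1), function(b) {
      mean(y[(bounds[b] + 1):bounds[b + 1]])
    }, numeric(1))
    if (is.unsorted(rev(means), strictly = FALSE)) next  # must be non-increasing
    fit <- rep(means, diff(bounds))
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# BH by the literal min-over-suffix step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# O(n*m) nearest-occupied-base distance
oracle_nearest <- function(genes, features) {
  vapply(seq_len(nrow(genes)), function(i) {
    f <- features[features$chrom == genes$chrom[i], , drop = FALSE]
    if (!nrow(f)) return(NA_real_)
    tss <- genes$tss[i]
    min(vapply(seq_len(nrow(f)), function(j) {
      if (tss >= f$start[j] && tss < f$end[j]) 0
      else min(abs(tss - f$start[j]), abs(tss - (f$end[j] - 1)))
    }, numeric(1)))
  }, numeric(1))
}

# exact conditional binomial p by explicit split enumeration
oracle_split_test <- function(xa, xb, pi_a) {
  tot <- xa + xb
  pr <- vapply(0:tot, function(k) {
    exp(lchoose(tot, k) + k * log(pi_a) + (tot - k) * log1p(-pi_a))
  }, numeric(1))
  sum(pr[pr <= pr[xa + 1] * (1 + 1e-9)])
}

# tiny deterministic fragment map straight from a fragment table
toy_map <- function(starts, ends, chrom = "chr1") {
  frs <- data.frame(chrom = chrom, start = as.integer(starts),
                    end = as.integer(ends),
                    index = seq_along(starts) - 1L, blind = TRUE)
  structure(list(fragments = stats::setNames(list(frs), chrom),
                 seqlengths = stats::setNames(max(ends), chrom),
                 scheme = cutter_scheme()),
            class = "FragmentMap")
}

# shared mid-size simulation scenario: one genome, ~2000 fragments
sim_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- make_genome(20260930, length = 5e5, gatc_rate = 0.004,
                            gtac_rate = 0.004)
      map <- fragment_map(genome)
      frs <- map$fragments[[1]]
      vpf <- frs[nrow(frs) %/% 2, ]
      vp <- viewpoint_spec("vp", vpf$chrom,
                           floor((vpf$start + vpf$end) / 2), map)
      cache <<- list(map = map, viewpoint = vp, n_frag = nrow(frs))
    }
    cache
  }
})
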