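genes_df <- function(tss, chrom = "chr1", class = "unchanged_expressed",
                     strand = "+") {
  data.frame(gene = sprintf("g%d", seq_along(tss)), chrom = chrom, tss = tss,
             strand = strand, class = class, stringsAsFactors = FALSE)
}

iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("nearest distance measures to the nearest occupied base", {
  g <- genes_df(1000)
  feats <- iv("chr1", c(880, 1500), c(900, 1600))
  expect_equal(nearest_distance(g, feats)$distance, 101)  # to base 899
  # TSS inside a peak
  expect_equal(nearest_distance(genes_df(1550), feats)$distance, 0)
  # no feature on the chromosome
  expect_message(
    d <- nearest_distance(genes_df(10, chrom = "chrZ"), feats)$distance,
    "missing")
  expect_true(is.na(d))
})

test_that("nearest distance equals O(n*m) brute force on random fixtures", {
  set.seed(202)
  for (i in 1:50) {
    ng <- sample(5:200, 1)
    nf <- sample(5:200, 1)
    g <- genes_df(sample.int(1e6, ng),
                  chrom = sample(c("chr1", "chr2"), ng, replace = TRUE))
    s <- sample.int(1e6, nf)
    feats <- iv(sample(c("chr1", "chr2"), nf, replace = TRUE),
                s, s + sample.int(500, nf))
    got <- suppressMessages(nearest_distance(g, feats)$distance)
    expect_equal(got, oracle_nearest(g, feats))
  }
})

test_that("window frequencies are class fractions relative to unchanged", {
  # every up gene has a peak at its TSS; half of the unchanged do
  g <- rbind(genes_df(seq(10000, 100000, by = 10000), class = "up"),
             genes_df(seq(210000, 300000, by = 10000)))
  feats <- iv("chr1",
              c(g$tss[g$class == "up"],
                g$tss[g$class == "unchanged_expressed"][1:5]) - 50,
              c(g$tss[g$class == "up"],
                g$tss[g$class == "unchanged_expressed"][1:5]) + 50)
  wf <- window_frequency(g, feats, windows = 1000)
  expect_equal(wf$RF[wf$class == "unchanged_expressed"], 1.0)
  expect_equal(wf$F[wf$class == "up"], 1.0)
  expect_equal(wf$RF[wf$class == "up"], 2.0)
  # w = 0 degenerates to TSS-overlap counting
  wf0 <- window_frequency(g, feats, windows = 0)
  expect_equal(wf0$F[wf0$class == "up"], 1.0)
  wf0b <- suppressWarnings(
    window_frequency(genes_df(99), iv("chr1", 100, 200), windows = 0))
  expect_equal(wf0b$F, 0)
  # empty reference class is an error; zero reference frequency a warning
  expect_error(window_frequency(genes_df(1, class = "up"), feats),
               "unchanged_expressed")
  expect_warning(
    wfz <- window_frequency(rbind(genes_df(5e5, class = "up"),
                                  genes_df(9e5)), feats, windows = 100),
    "missing")
  expect_true(is.na(wfz$RF[wfz$class == "up"]))
})

test_that("permutation null gives calibrated add-one p-values", {
  set.seed(303)
  pool <- genes_df(sample.int(1e6, 200))
  pool$distance <- rexp(200, 1 / 2e4)
  stat <- function(g) mean(g$distance)
  # a class drawn from the pool itself: p near 0.5-ish, never outside bounds
  cls <- pool[sample.int(200, 40), ]
  pn <- permutation_null(stat, cls, pool, n_draws = 500, seed = 9)
  expect_gte(pn$p_upper, 1 / 501)
  expect_lte(pn$p_upper, 1)
  # with a continuous statistic the tails overlap only in the +1 terms
  expect_equal(pn$p_upper + pn$p_lower, 1 + 1 / 501)
  # class = entire pool: every draw reproduces the observed statistic
  pn_all <- permutation_null(stat, pool, pool, n_draws = 100, seed = 9)
  expect_equal(pn_all$p_upper, 1)
  expect_equal(pn_all$p_lower, 1)
  # minimum attainable p with N = 5000 is 1/5001
  far <- pool[1:10, ]
  far$distance <- far$distance + 1e9
  pn_min <- permutation_null(stat, far, pool, n_draws = 5000, seed = 9)
  expect_equal(pn_min$p_upper, 1 / 5001)
  # pool smaller than the class is an error; seed is mandatory
  expect_error(permutation_null(stat, pool, pool[1:5, ], seed = 1),
               "smaller")
  expect_error(permutation_null(stat, cls, pool), "seed")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(304)
  pool <- genes_df(sample.int(1e6, 120))
  pool$distance <- rexp(120, 1 / 2e4)
  stat <- function(g) mean(g$distance)
  pvals <- vapply(1:200, function(i) {
    cls <- pool[sample.int(120, 30), ]
    permutation_null(stat, cls, pool, n_draws = 199, seed = 7000 + i)$p_upper
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mann_whitney exact branch matches rank-assignment enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)
  expect_equal(mw$method, "exact")
  set.seed(404)
  for (i in 1:30) {
    nx <- sample(1:6, 1)
    ny <- sample(max(1, 2 - nx):(10 - nx), 1)
    x <- runif(nx)
    y <- runif(ny)
    got <- mann_whitney(x, y)
    exp <- oracle_mw_exact(x, y)
    expect_equal(got$U, exp$U)
    expect_equal(got$p, exp$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("mann_whitney ties fall back to a close normal approximation", {
  x <- c(1, 1, 2, 2)
  expect_equal(mann_whitney(x, x)$method, "normal_approx")
  expect_equal(mann_whitney(x, x)$p, 1)
  # branches agree for moderate samples
  set.seed(405)
  diffs <- vapply(1:100, function(i) {
    x <- runif(7); y <- runif(7)
    exact <- oracle_mw_exact(x, y)$p
    approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    abs(exact - approx)
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
})

test_that("tissue-specific peaks have zero overlap with the merged union", {
  focal <- iv("chr1", c(100, 500), c(200, 600))
  others <- list(iv("chr1", 150, 250))
  out <- tissue_specific_peaks(focal, others)
  expect_equal(out$start, 500)
  expect_equal(tissue_specific_peaks(focal, list()), focal)
  # focal contained in the union: empty output
  expect_equal(nrow(tissue_specific_peaks(focal, list(iv("chr1", 0, 1000)))),
               0L)
  # 1 bp overlap suffices for removal
  expect_equal(nrow(tissue_specific_peaks(iv("chr1", 100, 200),
                                          list(iv("chr1", 199, 300)))), 0L)
  set.seed(505)
  for (i in 1:20) {
    s <- sample.int(1e5, 50)
    focal <- iv("chr1", s, s + sample.int(300, 50))
    others <- lapply(1:3, function(j) {
      s2 <- sample.int(1e5, 30)
      iv("chr1", s2, s2 + sample.int(300, 30))
    })
    out <- tissue_specific_peaks(focal, others)
    merged <- do.call(rbind, others)
    if (nrow(out)) {
      overl <- vapply(seq_len(nrow(out)), function(k) {
        any(out$start[k] < merged$end & out$end[k] > merged$start)
      }, logical(1))
      expect_false(any(overl))
    }
  }
})

test_that("meta-profiles standardize per chromosome and flip strands", {
  # constant track: z = 0 everywhere
  g <- genes_df(c(10000, 20000))
  track <- iv("chr1", 0, 1e5)
  track$score <- 3
  mp <- meta_profile(g, track)
  expect_equal(unique(mp$profiles$mean_z), 0)
  expect_equal(unique(mp$profiles$smoothed), 0)

  # spike at the TSS appears at position ~0 regardless of strand
  spike <- function(strand) {
    g1 <- genes_df(50000, strand = strand)
    tr <- rbind(iv("chr1", 40000, 49990), iv("chr1", 49990, 50010),
                iv("chr1", 50010, 60000))
    tr$score <- c(0, 10, 0)
    mp1 <- meta_profile(g1, tr, bin_width = 10)
    mp1$position[which.max(mp1$profiles$mean_z)]
  }
  expect_lt(abs(spike("+")), 10)
  expect_lt(abs(spike("-")), 10)

  # per-chromosome baselines cancel: identical shapes, identical z-profiles
  g2 <- rbind(genes_df(50000, chrom = "chrA"), genes_df(50000, chrom = "chrB"))
  tr2 <- rbind(
    data.frame(iv("chrA", c(48000, 49900, 50100), c(49900, 50100, 52000)),
               score = c(1, 2, 1)),
    data.frame(iv("chrB", c(48000, 49900, 50100), c(49900, 50100, 52000)),
               score = c(101, 102, 101)))
  mp2 <- meta_profile(g2, tr2)
  expect_equal(mp2$zvalues[1, ], mp2$zvalues[2, ])

  # uncovered positions count as zero and are tallied
  g3 <- genes_df(50000)
  tr3 <- iv("chr1", 49000, 51000)
  tr3$score <- 1
  expect_message(mp3 <- meta_profile(g3, tr3), "not covered")
  expect_gt(mp3$n_missing, 0)
})
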