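# build a CaptureProfile-shaped object from bare window f values, one side
profile_from_f <- function(f, side = "downstream", distance = NULL) {
  n <- length(f)
  if (is.null(distance)) distance <- seq_len(n) * 1000
  windows <- data.frame(
    window = seq_len(n), frag_first = seq_len(n) - 1L,
    frag_last = seq_len(n) + 28L, chrom = "chr1",
    start = seq_len(n) * 100L, end = seq_len(n) * 100L + 3000L,
    midpoint = seq_len(n) * 100L + 1500, distance = distance,
    side = side, c = as.integer(round(f * 60)), f = f,
    excluded = FALSE, truncated = FALSE, stringsAsFactors = FALSE)
  structure(list(viewpoint = list(name = "vp"), replicate = "r1",
                 window_size = 30L, step = 1L, windows = windows),
            class = "CaptureProfile")
}

# two-sided profile: mirrored distances around a viewpoint
profile_two_sided <- function(f_up, f_down) {
  up <- profile_from_f(f_up, "upstream")$windows
  down <- profile_from_f(f_down, "downstream")$windows
  down$window <- down$window + nrow(up)
  w <- rbind(up, down)
  structure(list(viewpoint = list(name = "vp"), replicate = "r1",
                 window_size = 30L, step = 1L, windows = w),
            class = "CaptureProfile")
}

test_that("PAVA equals brute-force level-set enumeration on small inputs", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    y <- round(runif(n), 3)
    fit <- contactscape:::pava_nonincreasing(y)
    expect_equal(fit, oracle_isotonic_decreasing(y), tolerance = 1e-10)
    # non-increasing
    expect_true(all(diff(fit) <= 1e-12))
    # within each level set the mean residual vanishes
    r <- y - fit
    for (lev in unique(fit)) {
      expect_lt(abs(mean(r[abs(fit - lev) < 1e-12])), 1e-12)
    }
  }
})

test_that("PAVA agrees with stats::isoreg on negated data", {
  set.seed(34)
  y <- runif(50)
  expect_equal(contactscape:::pava_nonincreasing(y),
               -stats::isoreg(seq_along(y), -y)$yf, tolerance = 1e-12)
})

test_that("monotone data fit exactly, with zero z-scores", {
  f <- seq(0.9, 0.1, length.out = 20)
  fit <- fit_decay(profile_two_sided(f, f))
  expect_equal(fit$yhat, fit$f)
  expect_equal(fit$z, rep(0, nrow(fit)))
  # constant data likewise
  fitc <- fit_decay(profile_two_sided(rep(0.4, 10), rep(0.4, 10)))
  expect_equal(unique(fitc$yhat), 0.4)
  expect_equal(fitc$z, rep(0, nrow(fitc)))
})

test_that("a spiked window dominates the z-scores", {
  set.seed(55)
  d <- seq(1000, 50000, by = 1000)
  base <- 0.5 * (d / 1000)^-1
  f <- pmin(1, base + rnorm(length(d), 0, 0.002))
  f <- pmax(f, 0)
  spiked <- f
  spiked[25] <- min(1, f[25] * 10)
  fit <- fit_decay(profile_two_sided(spiked, spiked))
  expect_equal(which.max(fit$z[fit$side == "upstream"]), 25L)
  expect_gt(max(fit$z), 2)
  # and removing the spike removes the signal
  fit0 <- fit_decay(profile_two_sided(f, f))
  expect_lt(max(abs(fit0$resid)), max(abs(fit$resid)))
})

test_that("degenerate inputs are handled per contract", {
  expect_error(fit_decay(profile_two_sided(rep(0.1, 3), rep(0.1, 10))),
               "insufficient windows")
  w <- testthat::capture_warnings(
    fit <- fit_decay(profile_two_sided(rep(0, 10), rep(0, 10))))
  expect_match(w, "zero", all = TRUE)
  expect_length(w, 2)  # one per side
  expect_equal(fit$z, rep(0, 20))
})

test_that("bh_adjust matches the step-up definition and p.adjust contract", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # q is monotone non-decreasing in p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("the consensus rule requires z in all replicates and q in one", {
  f <- seq(0.9, 0.1, length.out = 20)
  fits <- lapply(c("r1", "r2"), function(r) {
    fit <- fit_decay(profile_two_sided(f, f))
    attr(fit, "replicate") <- r
    fit
  })
  grid <- fits[[1]][, c("chrom", "start", "end", "window")]
  fake <- function(z1, z2, q1, q2, row = 1) {
    f2 <- fits
    f2[[1]]$z[row] <- z1; f2[[2]]$z[row] <- z2
    f2[[1]]$q[row] <- q1; f2[[2]]$q[row] <- q2
    score_contacts(f2)$consensus_significant[row]
  }
  expect_true(fake(2.5, 2.6, 0.01, 0.2))    # rule satisfied
  expect_false(fake(2.5, 1.9, 0.001, 0.001))  # z fails in one replicate
  expect_false(fake(3.0, 3.0, 0.2, 0.2))    # no replicate passes q
})

test_that("score_contacts rejects bad replicate structures", {
  f <- seq(0.9, 0.1, length.out = 20)
  fit <- fit_decay(profile_two_sided(f, f))
  expect_error(score_contacts(list(fit)), ">=2 replicates")
  other <- fit_decay(profile_two_sided(f[-1], f[-1]))
  expect_error(score_contacts(list(fit, other)), "mismatched window grids")
})

test_that("null profiles stay below the consensus false-call budget", {
  sc <- sim_scenario()
  n_seeds <- 25
  frac <- vapply(seq_len(n_seeds), function(s) {
    reads <- simulate_4c(sc$map, sc$viewpoint, seed = 1000 + s,
                         replicates = 2)
    fits <- lapply(names(reads), function(r) {
      fit_decay(capture_profile(reads[[r]], sc$map, sc$viewpoint,
                                replicate = r))
    })
    calls <- score_contacts(fits)
    mean(calls$consensus_significant)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("planted 10-fold contacts are recovered in both replicates", {
  sc <- sim_scenario()
  vp_idx <- sc$viewpoint$viewpoint_fragment_index
  enriched <- data.frame(frag_first = vp_idx + c(200L, -400L),
                         frag_last = vp_idx + c(229L, -371L),
                         fold = 10)
  hits <- vapply(1:25, function(s) {
    reads <- simulate_4c(sc$map, sc$viewpoint, seed = 3000 + s,
                         replicates = 2, enriched = enriched)
    fits <- lapply(names(reads), function(r) {
      fit_decay(capture_profile(reads[[r]], sc$map, sc$viewpoint,
                                replicate = r))
    })
    calls <- score_contacts(fits)
    sig <- calls[calls$consensus_significant, ]
    vapply(seq_len(nrow(enriched)), function(i) {
      any(sig$window %in%
            calls$window[fits[[1]]$frag_first <= enriched$frag_last[i] &
                           fits[[1]]$frag_last >= enriched$frag_first[i]])
    }, logical(1))
  }, logical(2))
  expect_gte(mean(hits), 0.9)
})
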