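test_that("binning conserves signal and matches a per-base oracle", {
  gm <- toy_genome(10000)
  set.seed(61)
  iv <- data.frame(start = sample(0:9500, 20),
                   value = runif(20, 0.5, 3))
  iv$end <- pmin(iv$start + sample(50:900, 20, replace = TRUE), 10000)
  trk <- bin_coverage(iv, gm, bin_width = 500)
  expect_equal(sum(trk$depth), sum(iv$value * (iv$end - iv$start)))
  # brute-force per-base accumulation
  base <- numeric(10000)
  for (i in seq_len(nrow(iv))) {
    idx <- (iv$start[i] + 1):iv$end[i]
    base[idx] <- base[idx] + iv$value[i]
  }
  oracle <- vapply(seq(0, 9500, by = 500), function(s) sum(base[(s + 1):(s + 500)]), 0)
  expect_equal(trk$depth, oracle)
})

test_that("binning handles wrap-around intervals and masks", {
  gm <- genome_map(10000, oric = 0,
                   masked_intervals = list(c(4000, 4500)))
  iv <- data.frame(start = 9800, end = 10000 + 300, value = 2)  # wraps origin
  trk <- bin_coverage(iv, gm, bin_width = 500)
  expect_equal(trk$depth[1], 2 * 300)
  expect_equal(trk$depth[20], 2 * 200)
  expect_true(all(trk$masked[9]))
  expect_equal(trk$depth[9], 0)
})

test_that("uniform coverage yields equal bins and flat normalization", {
  gm <- toy_genome(10000)
  iv <- data.frame(start = 0, end = 10000, value = 1.5)
  trk <- bin_coverage(iv, gm, bin_width = 1000)
  expect_true(all(trk$depth == 1500))
  cpm <- normalize_track(trk, gm, "cpm")
  expect_equal(sum(cpm$depth), 1e6)
  expect_identical(normalize_track(cpm, gm, "cpm"), cpm)  # idempotent
  ct <- normalize_track(trk, gm, "cpm+terminus")
  expect_equal(unname(ct$depth), rep(1, 10), tolerance = 1e-12)
  zero <- track_from_values(rep(0, 10), gm)
  expect_error(normalize_track(zero, gm, "cpm"), "zero")
})

test_that("smoothing leaves constants alone and removes spikes", {
  gm <- toy_genome(1e5)
  v <- rep(40, 100)
  sm <- smooth_and_trim(track_from_values(v, gm), span = 0.1)
  expect_equal(unname(sm$depth), v, tolerance = 1e-6)
  v2 <- v; v2[37] <- 4000
  sm2 <- smooth_and_trim(track_from_values(v2, gm), span = 0.1, trim_k = 5)
  expect_lt(max(abs(sm2$depth - 40)), 1)
})

test_that("replicate tracks are averaged before smoothing", {
  gm <- toy_genome(1e5)
  t1 <- track_from_values(rep(10, 100), gm)
  t2 <- track_from_values(rep(30, 100), gm)
  sm <- smooth_and_trim(list(t1, t2), span = 0.1)
  expect_equal(unname(sm$depth), rep(20, 100), tolerance = 1e-6)
})

test_that("loess smoothing tracks a rolling weighted-regression oracle", {
  gm <- toy_genome(4e5)
  n <- 400
  x <- seq_len(n)
  v <- 100 + 30 * sin(2 * pi * x / n * 3)
  sm <- smooth_and_trim(track_from_values(v, gm), span = 0.05)
  # oracle: local degree-1 regression with tricube weights over the span
  # window, on the circularly padded series
  pad <- 21
  xp <- c(v[(n - pad + 1):n], v, v[1:pad])
  k <- ceiling(0.05 * n)
  oracle <- vapply(seq_len(n), function(i) {
    j <- i + pad
    idx <- (j - k):(j + k)
    d <- abs(idx - j)
    q <- sort(d)[k + 1]
    w <- (1 - pmin(d / q, 1)^3)^3
    sum_w <- sum(w)
    xbar <- sum(w * idx) / sum_w
    ybar <- sum(w * xp[idx]) / sum_w
    b <- sum(w * (idx - xbar) * (xp[idx] - ybar)) / sum(w * (idx - xbar)^2)
    ybar + b * (j - xbar)
  }, 0)
  expect_lt(max(abs(sm$depth - oracle) / oracle), 0.01)
})

test_that("replicore asymmetry is 1 on symmetric tracks and reciprocal", {
  gm <- toy_genome(10000, oric = 5000)
  frac <- replichore_position(gm, seq(250, 9750, by = 500))$fraction
  v <- 2^(1 - frac)  # symmetric pyramid
  trk <- track_from_values(v, gm, bin_width = 500)
  for (locus in c(1200, 3600, 7800)) {
    expect_equal(replicore_asymmetry(trk, gm, locus), 1, tolerance = 1e-9)
  }
  # reciprocal identity on an asymmetric track
  set.seed(62)
  trk2 <- track_from_values(runif(20, 1, 5), gm, bin_width = 500)
  a <- replicore_asymmetry(trk2, gm, 1200)
  b <- replicore_asymmetry(trk2, gm, mirror_locus(gm, 1200))
  expect_equal(a * b, 1, tolerance = 1e-12)
  expect_error(replicore_asymmetry(trk2, gm, 5000), "oriC")
})

test_that("flat and pyramid profiles give the expected origin:terminus ratios", {
  gm <- toy_genome(100000, oric = 20000)
  flat <- track_from_values(rep(7, 100), gm)
  expect_equal(origin_terminus_ratio(flat, gm, window = 5000), 1)
  frac <- replichore_position(gm, seq(500, 99500, by = 1000))$fraction
  pyr <- track_from_values(2^(1 - frac), gm)
  expect_equal(origin_terminus_ratio(pyr, gm, window = 2000), 2,
               tolerance = 0.05)
  expect_error(origin_terminus_ratio(track_from_values(c(rep(1, 50), rep(0, 50)),
                                                       gm), gm, window = 2000),
               "terminus")
})

test_that("plateau detection flags constructed shelves and nothing else", {
  gm <- toy_genome(1e6, oric = 5e5)
  n <- 1000
  mids <- seq(500, 1e6 - 500, by = 1000)
  frac <- replichore_position(gm, mids)$fraction
  pyramid <- 400 * 2^(1 - frac)
  # strictly monotone pyramid: no plateau
  expect_equal(nrow(detect_degradation_plateau(
    track_from_values(pyramid, gm), gm)), 0)
  # flat shelf across oriC, stepped below the pyramid trend
  shelf <- pyramid
  in_shelf <- frac <= 0.3
  shelf[in_shelf] <- 0.5 * 400 * 2^0.7
  set.seed(63)
  noisy <- rpois(n, shelf)
  pl <- detect_degradation_plateau(track_from_values(noisy, gm), gm,
                                   min_length = 50)
  expect_equal(nrow(pl), 1)
  # planted shelf edges: fraction 0.3 on both replichores
  left_edge <- replichore_coord(gm, 0.3, "left")
  right_edge <- replichore_coord(gm, 0.3, "right")
  expect_lt(abs(pl$start - left_edge), 2000)
  expect_lt(abs(pl$end %% gm$length - right_edge), 2000)
})

test_that("noisy monotone pyramids produce no false plateaus", {
  gm <- toy_genome(1e6, oric = 5e5)
  mids <- seq(500, 1e6 - 500, by = 1000)
  frac <- replichore_position(gm, mids)$fraction
  lambda <- 400 * 2^(1 - frac)
  set.seed(64)
  false_hits <- vapply(1:20, function(i) {
    nrow(detect_degradation_plateau(track_from_values(rpois(length(lambda),
                                                            lambda), gm), gm))
  }, 0)
  expect_true(all(false_hits == 0))
})

test_that("orientation index is bounded and balanced tracks sit at 1/2", {
  gm <- toy_genome(100000, oric = 0)
  n <- 100
  set.seed(65)
  fwd <- rpois(n, 50); rev_ <- rpois(n, 50)
  trk <- coverage_track(seq(0, 99999, by = 1000), cbind(fwd = fwd, rev = rev_),
                        1000, 1e5)
  oi <- orientation_index(trk, gm)
  expect_true(all(abs(oi$oi[!is.na(oi$oi)]) <= 1))
  expect_equal(oi$away_fraction, 0.5, tolerance = 0.03)
  expect_lt(abs(mean(oi$oi, na.rm = TRUE)), 0.05)
  # all right-facing signal on the right replichore
  fwd2 <- numeric(n); fwd2[2:10] <- 100  # right replichore bins (oric = 0)
  trk2 <- coverage_track(seq(0, 99999, by = 1000),
                         cbind(fwd = fwd2, rev = numeric(n)), 1000, 1e5)
  oi2 <- orientation_index(trk2, gm)
  expect_equal(oi2$away_fraction, 1)
  expect_true(all(oi2$oi[2:10] == 1))
  expect_error(orientation_index(coverage_track(seq(0, 99999, by = 1000),
                                                cbind(fwd = numeric(n),
                                                      rev = numeric(n)),
                                                1000, 1e5), gm), "signal")
})

test_that("summaries are invariant under rotation of the coordinate origin", {
  len <- 100000
  shift <- 30000
  set.seed(66)
  iv <- data.frame(start = seq(0, len - 1000, by = 1000),
                   end = seq(1000, len, by = 1000),
                   value = runif(100, 1, 10))
  gm1 <- genome_map(len, oric = 10000)
  gm2 <- genome_map(len, oric = (10000 + shift) %% len)
  iv2 <- iv
  iv2$start <- (iv$start + shift) %% len
  iv2$end <- iv2$start + 1000
  t1 <- bin_coverage(iv, gm1, 1000)
  t2 <- bin_coverage(iv2, gm2, 1000)
  expect_equal(sum(t1$depth), sum(t2$depth))
  expect_equal(origin_terminus_ratio(t1, gm1, window = 5000),
               origin_terminus_ratio(t2, gm2, window = 5000), tolerance = 1e-9)
  expect_equal(replicore_asymmetry(t1, gm1, 25000),
               replicore_asymmetry(t2, gm2, (25000 + shift) %% len),
               tolerance = 1e-9)
})
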