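test_that("peak detection locates single and well-separated modes", {
  set.seed(51)
  one <- rnorm(1e4, 200, 20)
  pk <- detect_peaks(one)
  expect_equal(length(pk$positions), 1L)
  expect_lt(abs(pk$positions - 200), pk$bandwidth)

  two <- c(rnorm(5000, 100, 10), rnorm(5000, 400, 40))
  pk2 <- detect_peaks(two)
  expect_equal(length(pk2$positions), 2L)
  expect_lt(abs(pk2$positions[1] - 100) / 100, 0.02)
  expect_lt(abs(pk2$positions[2] - 400) / 400, 0.02)
})

test_that("a four-component DNA-content mixture matches the analytic density", {
  set.seed(52)
  mus <- c(1, 2, 4, 8) * 100
  vals <- unlist(lapply(mus, function(m) rnorm(8000, m, 0.1 * m)))
  pk <- detect_peaks(vals, bandwidth = 8)
  expect_equal(length(pk$positions), 4L)
  # oracle: modes of the analytic mixture density on a fine grid
  grid <- seq(0, 1200, by = 0.1)
  dens <- Reduce(`+`, lapply(mus, function(m) dnorm(grid, m, 0.1 * m) / 4))
  modes <- vapply(mus, function(m) {
    win <- grid > 0.7 * m & grid < 1.4 * m
    grid[win][which.max(dens[win])]
  }, 0)
  expect_true(all(abs(pk$positions - modes) / modes < 0.02))
})

test_that("peak detection is shift-equivariant", {
  set.seed(53)
  v <- c(rnorm(3000, 150, 12), rnorm(3000, 420, 30))
  p0 <- detect_peaks(v, bandwidth = 10)
  p1 <- detect_peaks(v + 75, bandwidth = 10)
  expect_equal(p1$positions, p0$positions + 75, tolerance = 1e-6)
  expect_error(detect_peaks(v, bandwidth = -1), "bandwidth")
  expect_error(detect_peaks(v[1:50]), "events")
})

test_that("calibration is exact on noise-free peaks and invertible", {
  cal <- fit_chromosome_calibration(c(100, 200, 400), c(1, 2, 4))
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r2, 1)
  expect_equal(signal_to_chromosomes(cal, 300), 3)
  # round trip: count(signal(n)) = n
  expect_equal(signal_to_chromosomes(cal, cal$intercept + cal$slope * c(1, 2, 4)),
               c(1, 2, 4))
  expect_error(fit_chromosome_calibration(c(100, 200), c(2, 2)), "distinct")
})

test_that("calibration slope is stable under peak-position noise", {
  set.seed(54)
  slopes <- replicate(100, {
    pos <- 100 * c(1, 2, 4) + rnorm(3, 0, 5)
    fit_chromosome_calibration(pos, c(1, 2, 4))$slope
  })
  expect_lt(abs(mean(slopes) - 100) / 100, 0.03)
})

test_that("chromosome fractions count calibrated windows", {
  cal <- fit_chromosome_calibration(c(100, 200, 400), c(1, 2, 4))
  all2 <- rep(200, 500)
  expect_equal(unname(chromosome_fractions(all2, cal, 2)), 1)
  expect_equal(unname(chromosome_fractions(all2, cal, 7)), 0)
  expect_error(chromosome_fractions(all2, cal, 2, tolerance = 0.5),
               "ambiguous")
  set.seed(55)
  mix <- c(rnorm(7000, 200, 10), rnorm(3000, 400, 20))
  fr <- chromosome_fractions(mix, cal, c(1, 2, 4), tolerance = 0.45)
  expect_lte(sum(fr), 1)
  expect_lt(abs(unname(fr["4"]) - 0.3), 0.02)
})

test_that("planted two-chromosome fraction survives the full round trip", {
  set.seed(56)
  n <- 20000
  equiv <- rep(c(1, 2, 4, 8), round(n * c(0.25, 0.30, 0.25, 0.20)))
  vals <- render_dapi_intensities(equiv, au_per_chromosome = 120, cv = 0.1,
                                  seed = 57)
  pk <- detect_peaks(vals)
  expect_equal(length(pk$positions), 4L)
  cal <- fit_chromosome_calibration(pk$positions, c(1, 2, 4, 8))
  expect_lt(abs(cal$slope - 120) / 120, 0.03)
  fr <- chromosome_fractions(vals, cal, 2, tolerance = 0.45)
  expect_lt(abs(unname(fr) - 0.30), 0.02)
})

test_that("reporter normalization matches a hand-computed table", {
  tab <- data.frame(
    sample_id = c("u1", "u2", "t1", "t2"),
    od600 = c(0.5, 0.7, 0.6, 0.4),
    fluor = c(1050, 1450, 2050, 2050),
    od_blank = 0.1, fluor_blank = 50
  )
  out <- reporter_bulk_normalize(tab, untreated_ids = c("u1", "u2"))
  per_od <- c(1000 / 0.4, 1400 / 0.6, 2000 / 0.5, 2000 / 0.3)
  expect_equal(out$normalized_value, per_od / mean(per_od[1:2]))
  expect_equal(mean(out$normalized_value[1:2]), 1)
  tab$od600[3] <- 0.05
  expect_error(reporter_bulk_normalize(tab, c("u1", "u2")), "od600")
})

test_that("plating viability reduces to cfu/ml arithmetic", {
  expect_equal(plating_viability(50, 50), 100)
  expect_equal(plating_viability(10, 100, 1, 1e4), 1e-3)
  # common rescaling of both dilutions cancels
  expect_equal(plating_viability(30, 60, 10, 100),
               plating_viability(30, 60, 10 * 7, 100 * 7))
  expect_error(plating_viability(10, 0), "titer")
  # batch against a hand oracle with mixed volumes
  sel <- c(12, 40, 7); tit <- c(300, 310, 305)
  out <- plating_viability(sel, tit, selective_dilution = 1,
                           titer_dilution = 1e3,
                           selective_volume = 0.1, titer_volume = 0.1)
  expect_equal(out, 100 * sel / (tit * 1e3))
})

test_that("exponential increment reads the 5.5-6.5 h window", {
  t15 <- seq(0, 10, by = 0.25)  # 15-min cadence
  expect_equal(exponential_increment(t15, 0.1 * t15), 0.1)
  expect_equal(exponential_increment(t15, rep(0.3, length(t15))), 0)
  od <- 0.01 * exp(0.6 * t15)
  expect_equal(exponential_increment(t15, od),
               0.01 * (exp(0.6 * 6.5) - exp(0.6 * 5.5)))
  expect_error(exponential_increment(c(0, 1, 2), c(0.1, 0.2, 0.3)), "7.5 min")
})
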