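ecoli_map <- function() genome_map(4641652, oric = 3925744)

test_that("a single unobstructed fork pair completes to two chromosomes", {
  tr <- replication_truth(ecoli_map(), generations_overlap = 0)
  cl <- simulate_replication_cells(tr, 200, seed = 1)
  expect_true(all(cl$state == "complete"))
  expect_equal(chromosome_equivalents(cl), rep(2, 200))
  prof <- suppressWarnings(population_copy_profile(cl, bin_width = 10000))
  expect_true(all(prof == 2))
})

test_that("reset reverts a full replication round; Gam freezes intermediates", {
  gm <- ecoli_map()
  stall <- replichore_coord(gm, 0.75, "left")
  tr <- replication_truth(gm, generations_overlap = 1, stall_locus = stall,
                          p_stall = 1, p_rearend_given_stall = 1,
                          gam_mode = FALSE)
  cl <- simulate_replication_cells(tr, 500, seed = 2)
  eq <- chromosome_equivalents(cl)
  # event bookkeeping oracle: with two rounds, cells whose older round is
  # still behind the blockage (age < 2 * 0.75 - 1) stall it, the trailing
  # round rear-ends and is degraded: 4 -> 2 exactly. In the remaining cells
  # only the young round is behind the blockage; with no trailing fork it
  # stays stalled: 4 - 2 * (1 - 0.75) / 2 = 3.75 equivalents.
  reset <- cl$state == "reset"
  expect_equal(reset, cl$age < 2 * 0.75 - 1)
  expect_equal(eq[reset], rep(2, sum(reset)))
  expect_equal(eq[!reset], rep(3.75, sum(!reset)))
  expect_true(all(cl$stalled_round[reset] == 1))

  trg <- replication_truth(gm, generations_overlap = 1, stall_locus = stall,
                           p_stall = 1, p_rearend_given_stall = 1,
                           gam_mode = TRUE)
  clg <- simulate_replication_cells(trg, 500, seed = 2)
  eqg <- chromosome_equivalents(clg)
  frozen <- clg$state == "gam_frozen"
  expect_equal(frozen, reset)  # same seed, same event draws
  expect_true(all(eqg[frozen] %% 1 != 0))  # stabilized non-integer content
  # protected ends retain more DNA than degradation
  expect_true(all(eqg[frozen] > eq[reset]))
})

test_that("parental DNA is never degraded (copy number stays >= 1)", {
  gm <- ecoli_map()
  stall <- replichore_coord(gm, 0.55, "left")
  for (gam in c(FALSE, TRUE)) {
    tr <- replication_truth(gm, generations_overlap = 3, stall_locus = stall,
                            p_stall = 1, p_rearend_given_stall = 1,
                            gam_mode = gam)
    cl <- simulate_replication_cells(tr, 100, seed = 3)
    for (at in c("runout", "reset", "exponential")) {
      prof <- suppressWarnings(population_copy_profile(cl, bin_width = 20000,
                                                       at = at))
      expect_true(all(prof >= 1))
    }
  }
})

test_that("exponential-phase profiles follow the age-structure integral", {
  gm <- ecoli_map()
  for (ov in 0:1) {
    tr <- replication_truth(gm, generations_overlap = ov)
    cl <- simulate_replication_cells(tr, 3000, seed = 4 + ov)
    prof <- suppressWarnings(population_copy_profile(cl, bin_width = 20000,
                                                     at = "exponential"))
    starts <- seq(0, gm$length - 1, by = 20000)
    mids <- (starts + pmin(starts + 20000, gm$length)) / 2
    frac <- replichore_position(gm, mids)$fraction
    expected <- expected_exponential_copy(frac, ov + 1)
    expect_lt(max(abs(prof - expected) / expected), 0.06)
  }
})

test_that("rendered run-out depth is Poisson-consistent and deterministic", {
  tr <- replication_truth(ecoli_map(), generations_overlap = 1)
  cl <- simulate_replication_cells(tr, 100, seed = 5)
  cov1 <- suppressWarnings(render_runout_coverage(cl, bin_width = 1000,
                                                  depth = 200, seed = 6))
  cov2 <- suppressWarnings(render_runout_coverage(cl, bin_width = 1000,
                                                  depth = 200, seed = 6))
  expect_identical(cov1, cov2)
  # completed population: flat expectation, variance/mean near 1
  v <- cov1$depth
  expect_equal(var(v) / mean(v), 1, tolerance = 0.1)
  expect_equal(mean(v), 200, tolerance = 0.02)
})

test_that("replication truths validate their geometry", {
  gm <- ecoli_map()
  expect_error(replication_truth(gm, stall_locus = -5, p_stall = 1),
               "outside")
  expect_error(replication_truth(gm, p_stall = 0.5), "stall_locus")
  tr <- replication_truth(gm, generations_overlap = 2,
                          stall_locus = replichore_coord(gm, 0.45, "left"),
                          p_stall = 1)
  expect_equal(tr$geometry$stall_fraction, 0.45, tolerance = 1e-6)
  expect_equal(tr$geometry$sister_fraction, 0.45 + 1 / 3, tolerance = 1e-6)
  rp <- replichore_position(gm, tr$geometry$sister_fork_locus)
  expect_equal(rp$replichore, "right")
  expect_error(simulate_replication_cells(tr, 0, seed = 1))
  expect_error(render_runout_coverage(
    structure(data.frame(), class = c("replication_cells", "data.frame"),
              truth = tr)), "empty")
})
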