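make_cm <- function(m, genes_per = 1) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  count_matrix(m, gene = paste0("gene", ceiling(seq_len(nrow(m)) / genes_per)))
}

test_that("size factors recover simple rescalings", {
  m <- matrix(rpois(200, 50) + 1, ncol = 2,
              dimnames = list(NULL, c("c_pre_1", "c_pre_2")))
  m[, 2] <- m[, 1]
  rownames(m) <- paste0("g", 1:100)
  expect_equal(unname(estimate_size_factors(make_cm(m))), c(1, 1))

  m2 <- m
  m2[, 2] <- 2 * m2[, 1]
  sf <- estimate_size_factors(make_cm(m2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("size factors equal a brute-force median-of-ratios oracle", {
  set.seed(21)
  m <- matrix(rnbinom(200, mu = 80, size = 5), ncol = 4,
              dimnames = list(paste0("g", 1:50),
                              paste0("c_pre_", 1:4)))
  sf <- estimate_size_factors(make_cm(m))
  # oracle: direct implementation
  keep <- apply(m > 0, 1, all)
  geo <- exp(rowMeans(log(m[keep, ])))
  raw <- apply(m[keep, ] / geo, 2, median)
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
  # scale equivariance up to geometric renormalization
  m3 <- m
  m3[, 3] <- m3[, 3] * 3
  sf3 <- estimate_size_factors(make_cm(m3))
  expect_equal(unname(sf3[3] / sf[3] / (sf3[1] / sf[1])), 3, tolerance = 1e-9)
})

test_that("size factors agree with the count-modelling reference", {
  skip_if_not_installed("DESeq2")
  set.seed(22)
  # odd guide count: the two implementations tie-break even-length medians
  # differently (arithmetic vs geometric mean of the middle ratios)
  m <- matrix(rnbinom(606, mu = 200, size = 8) + 1, ncol = 6,
              dimnames = list(paste0("g", 1:101), paste0("c_pre_", 1:6)))
  sf <- estimate_size_factors(make_cm(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("all-zero guides in some sample break the reference set informatively", {
  m <- matrix(c(0, 5, 10, 0), 2,
              dimnames = list(c("g1", "g2"), c("c_pre_1", "c_pre_2")))
  expect_error(estimate_size_factors(make_cm(m)), "pseudo-reference")
})

test_that("dispersion estimation recovers the simulation regimes", {
  set.seed(23)
  # Poisson counts: trended dispersion near 0
  mp <- matrix(rpois(300 * 40, 500), nrow = 300,
               dimnames = list(paste0("g", 1:300),
                               paste0("c_", rep(c("pre", "post"), each = 20),
                                      "_", rep(1:20, 2))))
  modp <- estimate_dispersions(make_cm(mp))
  expect_lt(median(modp$dispersions), 0.005)

  # constant counts across replicates: raw dispersion exactly 0
  mc <- matrix(700, nrow = 5, ncol = 4,
               dimnames = list(paste0("g", 1:5),
                               c("c_pre_1", "c_pre_2", "c_post_1", "c_post_2")))
  modc <- estimate_dispersions(make_cm(mc))
  expect_true(all(modc$dispersion_raw == 0))

  # NB alpha = 0.05 at mean 1000, 50 replicates: trend recovers alpha
  mn <- matrix(rnbinom(400 * 100, mu = 1000, size = 1 / 0.05), nrow = 400,
               dimnames = list(paste0("g", 1:400),
                               paste0("c_", rep(c("pre", "post"), each = 50),
                                      "_", rep(1:50, 2))))
  modn <- estimate_dispersions(make_cm(mn))
  expect_true(median(modn$dispersions) > 0.03 && median(modn$dispersions) < 0.07)

  expect_error(estimate_dispersions(make_cm(mc[, c(1, 3), drop = FALSE])),
               "replicates")
})

test_that("guide fold changes recover planted ratios", {
  set.seed(24)
  n <- 200
  pre <- matrix(rpois(n * 2, 4000), n)
  post <- matrix(rpois(n * 2, 4000), n)
  post[1:50, ] <- matrix(rpois(50 * 2, 16000), 50)  # 4x
  m <- cbind(pre, post)
  colnames(m) <- paste0("c_", rep(c("pre", "post"), each = 2), "_", rep(1:2, 2))
  rownames(m) <- paste0("g", 1:n)
  cm <- make_cm(m)
  sf <- rep(1, 4); names(sf) <- colnames(m)
  mod <- estimate_dispersions(cm, sf)
  lfc <- guide_log2fc(cm, mod, "c")
  expect_equal(median(lfc$lfc[1:50]), 2, tolerance = 0.05)
  expect_equal(median(lfc$lfc[51:n]), 0, tolerance = 0.05)
  # null guides: lfc within 2 SE of zero for the vast majority
  frac_ok <- mean(abs(lfc$lfc[51:n]) <= 2 * lfc$se[51:n])
  expect_gte(frac_ok, 0.9)
})

test_that("gene aggregation uses the median and drops empty genes", {
  gl <- data.frame(
    guide_id = paste0("g", 1:8),
    gene = c(rep("one", 1), rep("robust", 5), rep("low", 2)),
    lfc = c(1.7, -3, -3, 0, -3, -3, 5, 5),
    se = 0.1, mean_pre = c(rep(100, 6), 1, 1),
    mean_post = 100,
    low_coverage = c(rep(FALSE, 6), TRUE, TRUE)
  )
  attr(gl, "condition") <- "c"
  expect_warning(gf <- aggregate_gene_fitness(gl), "dropped")
  expect_equal(gf$lfc[gf$gene == "one"], 1.7)
  expect_equal(gf$lfc[gf$gene == "robust"], -3)  # median shrugs off inactive guide
  expect_false("low" %in% gf$gene)
  expect_equal(gf$n_guides[gf$gene == "robust"], 5L)
})
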