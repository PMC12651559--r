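#' Ground truth for a multifork replication run-out population
#'
#' Describes an exponential-phase population of circular chromosomes with
#' `generations_overlap` extra cohabiting replication rounds (0 = a single
#' active round; a completed run-out then yields `2^(overlap+1)` chromosomes
#' per cell), an optional head-on blockage locus at which leading forks stall,
#' fork rear-ending, and RecBCD-style degradation of the rear-ended nascent
#' DNA. Degradation runs from the rear-end site through *oriC* to the
#' sister-replichore fork position; with `gam_mode` the DNA end is protected
#' and the intermediate is frozen instead.
#'
#' Geometry is deterministic given the truth: with `G = overlap + 1` fork
#' generations spaced one initiation interval (`1/G` of a replichore) apart,
#' the trailing fork closes that interval to rear-end, during which the
#' stalled round's sister replisome advances the same interval. The
#' sister-fork locus is therefore `1/G` beyond the stall fraction on the
#' sister replichore.
#'
#' @param genome A [genome_map()] (or genome length; *oriC* then defaults
#'   to 0).
#' @param generations_overlap Extra cohabiting replication rounds (>= 0).
#' @param stall_locus Coordinate of the blockage (bp), or `NULL` for an
#'   unobstructed population.
#' @param p_stall Probability that a cell's leading fork stalls at the
#'   blockage.
#' @param p_rearend_given_stall Probability that the trailing fork rear-ends
#'   a stalled fork (requires a trailing round).
#' @param gam_mode If `TRUE`, DNA ends are protected: no degradation,
#'   intermediates are stabilized.
#' @return List of class `replication_truth`, including derived fields
#'   `rear_end_locus` and `sister_fork_locus` (bp).
#' @export
replication_truth <- function(genome, generations_overlap = 0,
                              stall_locus = NULL, p_stall = 0,
                              p_rearend_given_stall = 1, gam_mode = FALSE) {
  if (!inherits(genome, "genome_map")) genome <- genome_map(genome, oric = 0)
  g <- as.integer(generations_overlap)
  stopifnot(g >= 0)
  stop_if_not_scalar_prob(p_stall, "p_stall")
  stop_if_not_scalar_prob(p_rearend_given_stall, "p_rearend_given_stall")
  G <- g + 1L
  geom <- NULL
  if (!is.null(stall_locus)) {
    if (stall_locus < 0 || stall_locus >= genome$length) {
      stop("stall_locus outside genome", call. = FALSE)
    }
    rp <- replichore_position(genome, stall_locus)
    x_r <- min(1, rp$fraction + 1 / G)
    sister_side <- if (rp$replichore == "left") "right" else "left"
    geom <- list(
      stall_fraction = rp$fraction, stall_replichore = rp$replichore,
      sister_fraction = x_r,
      rear_end_locus = stall_locus,
      sister_fork_locus = replichore_coord(genome, x_r, sister_side)
    )
  } else if (p_stall > 0) {
    stop("p_stall > 0 requires a stall_locus", call. = FALSE)
  }
  structure(
    list(genome = genome, generations_overlap = g, G = G,
         stall_locus = stall_locus, p_stall = p_stall,
         p_rearend_given_stall = p_rearend_given_stall,
         gam_mode = isTRUE(gam_mode), geometry = geom),
    class = "replication_truth"
  )
}

#' Simulate per-cell fork configurations through a replication run-out
#'
#' Cells are drawn from the steady-state exponential age distribution
#' (density `2 ln2 * 2^(-a)`, `a` in `[0, 1)`); a cell of age `a` carries `G`
#' fork-generation rounds at replichore fractions `(a + G - j)/G`
#' (`j = 1..G`, oldest first), round `j` on `2^(j-1)` sister structures.
#' During run-out (initiation and division blocked, forks finish), the oldest
#' round still behind the blockage stalls with `p_stall`; its trailing round
#' rear-ends with `p_rearend_given_stall`, after which the rear-ended nascent
#' DNA is degraded (reverting one replication round) unless `gam_mode`
#' protects the ends and freezes the intermediate.
#'
#' @param truth A [replication_truth()].
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @return Object of class `replication_cells`: a data.frame (`age`, `state`,
#'   `stalled_round`) with the truth attached as an attribute. States are
#'   `complete`, `stalled` (blockage, no rear-end), `reset` (rear-ended and
#'   degraded), `gam_frozen` (rear-ended, ends protected).
#' @export
simulate_replication_cells <- function(truth, n_cells, seed) {
  stopifnot(inherits(truth, "replication_truth"), n_cells >= 1)
  n_cells <- as.integer(n_cells)
  G <- truth$G
  cells <- with_seed(seed, {
    # inverse-CDF draw from F(a) = 2 (1 - 2^(-a))
    age <- -log2(1 - runif(n_cells) / 2)
    state <- rep("complete", n_cells)
    stalled_round <- rep(NA_integer_, n_cells)
    if (!is.null(truth$geometry) && truth$p_stall > 0) {
      x_s <- truth$geometry$stall_fraction
      # round j sits at (a + G - j)/G; oldest round behind the blockage:
      # smallest j with (a + G - j)/G < x_s
      jstar <- G - floor(G * x_s - age)  # may exceed G (none behind)
      jstar <- ifelse(jstar >= 1 & jstar <= G, jstar, NA_integer_)
      hit <- !is.na(jstar) & (runif(n_cells) < truth$p_stall)
      has_trailer <- hit & jstar < G
      rear <- has_trailer & (runif(n_cells) < truth$p_rearend_given_stall)
      state[hit] <- "stalled"
      state[rear] <- if (truth$gam_mode) "gam_frozen" else "reset"
      stalled_round[hit] <- as.integer(jstar[hit])
    }
    data.frame(age = age, state = state, stalled_round = stalled_round)
  })
  attr(cells, "truth") <- truth
  class(cells) <- c("replication_cells", "data.frame")
  cells
}

#' @export
print.replication_cells <- function(x, ...) {
  truth <- attr(x, "truth")
  cat(sprintf("<replication_cells> %d cells, %d fork generation(s)\n",
              nrow(x), truth$G))
  print(table(x$state))
  invisible(x)
}

# Per-cell, per-round replicated extents (fractions of each replichore, on
# the stall side and the sister side) at one of two epochs:
#  * "runout": end of the run-out. Unimpeded rounds complete; a stalled
#    round's blocked fork stays at the stall fraction while its sister
#    completes; gam-frozen rounds are fixed at their rear-end extent; reset
#    removes the rear-ended round entirely (the degraded tract is re-entered
#    only through a new initiation, which the run-out blocks).
#  * "reset": snapshot at each cell's stall-resolution epoch (rear-end time,
#    or one initiation interval after the stall when no trailer exists).
# Returns a list of G x 2 matrices (columns: stall-side arm, sister-side arm)
# and, per cell, the multiplicative weight 2^(j-1) per round; removed rounds
# have extent NA.
cell_round_extents <- function(cells, at = c("runout", "reset", "exponential")) {
  at <- match.arg(at)
  truth <- attr(cells, "truth")
  G <- truth$G
  geom <- truth$geometry
  x_s <- if (!is.null(geom)) geom$stall_fraction else NA_real_
  lapply(seq_len(nrow(cells)), function(i) {
    a <- cells$age[i]
    st <- cells$state[i]
    js <- cells$stalled_round[i]
    q <- (a + G - seq_len(G)) / G
    ext <- matrix(NA_real_, nrow = G, ncol = 2,
                  dimnames = list(NULL, c("stall_arm", "sister_arm")))
    if (at == "exponential") {
      ext[, "stall_arm"] <- q
      ext[, "sister_arm"] <- q
    } else if (at == "runout") {
      ext[, ] <- 1
      if (st == "stalled" || st == "gam_frozen") {
        ext[js, "stall_arm"] <- x_s
        if (js < G) ext[(js + 1):G, "stall_arm"] <- x_s  # queued behind
        if (st == "gam_frozen") ext[js + 1L, ] <- x_s    # frozen intermediate
      } else if (st == "reset") {
        ext[js + 1L, ] <- NA  # degraded round
      }
    } else {
      # snapshot epoch
      tau <- if (st %in% c("reset", "gam_frozen")) {
        x_s - q[js + 1L]
      } else if (st == "stalled") {
        (x_s - q[js]) + 1 / G
      } else if (!is.null(geom)) {
        max(0, x_s - q[G]) + 1 / G
      } else {
        stop("snapshot rendering requires a stall locus in the truth",
             call. = FALSE)
      }
      pos <- pmin(q + tau, 1)
      ext[, "stall_arm"] <- pos
      ext[, "sister_arm"] <- pos
      if (!is.na(js)) {
        ext[js, "stall_arm"] <- x_s
        if (js < G) ext[(js + 1):G, "stall_arm"] <- pmin(pos[(js + 1):G], x_s)
        if (st == "reset") ext[js + 1L, ] <- NA
        if (st == "gam_frozen") ext[js + 1L, ] <- x_s
      }
    }
    ext
  })
}

#' Chromosome equivalents per cell at the end of the run-out
#'
#' Real-valued genome equivalents (1 = one complete chromosome): cells that
#' complete the run-out hold `2^(overlap+1)` chromosomes; a reset reverts one
#' full round (e.g. 4 -> 2); stalled or Gam-frozen intermediates leave
#' non-integer equivalents.
#'
#' @param cells A [simulate_replication_cells()] population.
#' @return Numeric vector, one value per cell.
#' @export
chromosome_equivalents <- function(cells) {
  stopifnot(inherits(cells, "replication_cells"))
  truth <- attr(cells, "truth")
  mult <- 2^(seq_len(truth$G) - 1)
  exts <- cell_round_extents(cells, at = "runout")
  vapply(exts, function(e) {
    frac <- rowMeans(e)          # each arm is half the genome
    1 + sum(mult * frac, na.rm = TRUE)
  }, 0)
}

#' Render a sequencing coverage track from a replication population
#'
#' Computes the population mean per-locus copy number and samples per-bin
#' read depths as Poisson around `mean copy * depth / overall mean copy`
#' (so the track averages `depth` reads per bin), unnormalized.
#'
#' Three epochs can be rendered: `"runout"` (completed run-out; flat for an
#' unobstructed population), `"exponential"` (no run-out; the classic
#' origin-to-terminus pyramid, origin:terminus ratio `2^G`), and `"reset"`
#' (snapshot at the stall-resolution epoch; in degradation-competent cells
#' the tract from the rear-end site through *oriC* to the sister-fork locus
#' has been resected to the parental single copy, leaving a depressed
#' plateau with sharp boundaries at the planted loci).
#'
#' @param cells A [simulate_replication_cells()] population.
#' @param genome A [genome_map()]; defaults to the truth's genome.
#' @param bin_width Bin width (bp).
#' @param depth Mean reads per bin.
#' @param at Epoch to render (see Details).
#' @param seed Integer seed for the Poisson sampling.
#' @return A [coverage_track()] (unstranded, raw counts).
#' @export
render_runout_coverage <- function(cells, genome = NULL, bin_width = 1000,
                                   depth = 100,
                                   at = c("runout", "exponential", "reset"),
                                   seed = 1) {
  stopifnot(inherits(cells, "replication_cells"), depth > 0)
  at <- match.arg(at)
  truth <- attr(cells, "truth")
  if (is.null(genome)) genome <- truth$genome
  mean_copy <- population_copy_profile(cells, genome, bin_width, at)
  bins <- make_bins(genome$length, bin_width)
  lambda <- mean_copy * depth / mean(mean_copy)
  counts <- with_seed(seed, rpois(length(lambda), lambda))
  coverage_track(bin_starts = bins$start, depth = counts,
                 bin_width = bin_width, genome_length = genome$length,
                 units = "raw")
}

#' Population mean per-locus copy number
#'
#' The noiseless expectation underlying [render_runout_coverage()]: mean
#' chromosomal copy number per bin across the population at the requested
#' epoch. Parental DNA is never degraded, so the profile is always >= 1.
#'
#' @inheritParams render_runout_coverage
#' @return Numeric vector, one mean copy number per bin.
#' @export
population_copy_profile <- function(cells, genome = NULL, bin_width = 1000,
                                    at = c("runout", "exponential", "reset")) {
  stopifnot(inherits(cells, "replication_cells"))
  if (nrow(cells) == 0) stop("empty population", call. = FALSE)
  at <- match.arg(at)
  truth <- attr(cells, "truth")
  if (is.null(genome)) genome <- truth$genome
  bins <- make_bins(genome$length, bin_width)
  mids <- (bins$start + bins$end) / 2
  rp <- replichore_position(genome, mids)
  geom <- truth$geometry
  stall_side <- if (!is.null(geom)) geom$stall_replichore else "left"
  on_stall_arm <- rp$replichore == stall_side
  G <- truth$G
  mult <- 2^(seq_len(G) - 1)

  exts <- cell_round_extents(cells, at = at)
  in_tract <- rep(FALSE, length(mids))
  if (at == "reset" && !is.null(geom)) {
    in_tract <- (on_stall_arm & rp$fraction <= geom$stall_fraction) |
      (!on_stall_arm & rp$fraction <= geom$sister_fraction)
  }
  total <- numeric(length(mids))
  for (i in seq_len(nrow(cells))) {
    e <- exts[[i]]
    cc <- numeric(length(mids))
    for (j in seq_len(G)) {
      if (is.na(e[j, 1])) next
      cc <- cc + mult[j] * ((on_stall_arm & rp$fraction <= e[j, "stall_arm"]) |
                            (!on_stall_arm & rp$fraction <= e[j, "sister_arm"]))
    }
    if (at == "reset" && cells$state[i] == "reset") cc[in_tract] <- 0
    total <- total + cc
  }
  1 + total / nrow(cells)
}

#' Render per-cell DAPI intensities
#'
#' Each cell's intensity is normal around `chromosome equivalents *
#' au_per_chromosome` with standard deviation `cv * mean`, truncated at 0 --
#' the DNA-content readout of a run-out flow-cytometry experiment.
#'
#' @param cells A [simulate_replication_cells()] population, or a numeric
#'   vector of chromosome equivalents.
#' @param au_per_chromosome Fluorescence units per chromosome.
#' @param cv Coefficient of variation of the optical readout (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of intensities (AU).
#' @export
render_dapi_intensities <- function(cells, au_per_chromosome = 100, cv = 0.1,
                                    seed = 1) {
  stopifnot(cv > 0)
  equiv <- if (inherits(cells, "replication_cells")) {
    chromosome_equivalents(cells)
  } else {
    stopifnot(is.numeric(cells), all(cells > 0))
    cells
  }
  mu <- equiv * au_per_chromosome
  with_seed(seed, pmax(0, rnorm(length(mu), mean = mu, sd = cv * mu)))
}
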