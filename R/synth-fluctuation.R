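#' Ground truth for a simulated fluctuation assay
#'
#' @param m Expected mutation events per culture (>= 0).
#' @param n_final Final cells per culture at saturation.
#' @param n_cultures Number of parallel cultures (the classic design uses 10
#'   experimental cultures per assay).
#' @param plating_fraction Fraction of each culture plated on selection.
#' @return List of class `fluctuation_truth`.
#' @export
fluctuation_truth <- function(m, n_final = 1e9, n_cultures = 10,
                              plating_fraction = 1) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0)
  stopifnot(n_final >= 1, n_cultures >= 1)
  stop_if_not_scalar_prob(plating_fraction, "plating_fraction", open_left = TRUE)
  structure(list(m = m, n_final = n_final, n_cultures = as.integer(n_cultures),
                 plating_fraction = plating_fraction, mutant_fitness = 1),
            class = "fluctuation_truth")
}

#' Simulate Luria-Delbruck mutant counts
#'
#' Per culture, the number of mutation events is Poisson(`m`); each event
#' founds a clone of size `floor(1/U)` with `U ~ Uniform(0, 1)` -- the exact
#' Lea-Coulson construction whose clone-size law `P(size = k) = 1/(k(k+1))`
#' underlies the Ma-Sandri-Sarkar recursion. Clone sizes are capped at
#' `n_final` and the total is thinned binomially by the plating fraction.
#'
#' @param truth A [fluctuation_truth()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return A [fluctuation_experiment()] whose `titer` is `n_final`.
#' @export
simulate_luria_delbruck <- function(truth, seed) {
  stopifnot(inherits(truth, "fluctuation_truth"))
  counts <- with_seed(seed, {
    n_events <- rpois(truth$n_cultures, truth$m)
    total <- numeric(truth$n_cultures)
    n_all <- sum(n_events)
    if (n_all > 0) {
      sizes <- pmin(floor(1 / runif(n_all)), truth$n_final)
      culture <- rep.int(seq_len(truth$n_cultures), n_events)
      agg <- rowsum(sizes, culture)
      total[as.integer(rownames(agg))] <- pmin(agg[, 1], truth$n_final)
    }
    if (truth$plating_fraction < 1) {
      small <- total <= .Machine$integer.max
      # thin huge jackpots in expectation to avoid integer overflow
      total[small] <- rbinom(sum(small), as.integer(total[small]),
                             truth$plating_fraction)
      total[!small] <- round(total[!small] * truth$plating_fraction)
    }
    total
  })
  fluctuation_experiment(counts, titer = truth$n_final,
                         plating_fraction = truth$plating_fraction)
}
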