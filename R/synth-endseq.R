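#' Ground truth for a stranded DNA-end (END-seq style) track
#'
#' One-ended sites -- free duplex ends from fork rear-ending -- emit signal
#' on exactly one strand, the one facing away from the replication origin
#' along the site's replichore; two-ended breaks emit equally on both
#' strands.
#'
#' @param end_sites Site coordinates (bp).
#' @param one_ended_fraction Fraction of sites that are one-ended; the first
#'   `round(f * n)` sites are assigned one-ended so the planted fraction is
#'   exact.
#' @param depth Expected reads per site.
#' @param noise Poisson background per bin per strand.
#' @return List of class `endedness_truth`.
#' @export
endedness_truth <- function(end_sites, one_ended_fraction, depth = 2000,
                            noise = 0.1) {
  stopifnot(is.numeric(end_sites), length(end_sites) >= 1)
  stop_if_not_scalar_prob(one_ended_fraction, "one_ended_fraction")
  stopifnot(depth > 0, noise >= 0)
  structure(list(end_sites = end_sites,
                 one_ended_fraction = one_ended_fraction,
                 depth = depth, noise = noise),
            class = "endedness_truth")
}

#' Simulate a stranded DNA-end coverage track
#'
#' @param truth An [endedness_truth()].
#' @param genome A [genome_map()]; sites must lie within it.
#' @param bin_width Bin width in bp.
#' @param seed Integer seed.
#' @return A stranded [coverage_track()] (columns `fwd`, `rev`); "right-
#'   facing" ends are forward-strand signal.
#' @export
simulate_endseq_track <- function(truth, genome, bin_width = 1000, seed = 1) {
  stopifnot(inherits(truth, "endedness_truth"), inherits(genome, "genome_map"))
  sites <- truth$end_sites
  if (any(sites < 0 | sites >= genome$length)) {
    stop("end sites outside genome", call. = FALSE)
  }
  bins <- make_bins(genome$length, bin_width)
  n <- length(bins$start)
  n_one <- round(truth$one_ended_fraction * length(sites))
  one_ended <- seq_along(sites) <= n_one
  right_rep <- replichore_position(genome, sites)$replichore == "right"
  bin_idx <- findInterval(sites, bins$start)
  fwd <- numeric(n)
  rev_ <- numeric(n)
  with_seed(seed, {
    for (k in seq_along(sites)) {
      if (one_ended[k]) {
        reads <- rpois(1, truth$depth)
        # away from oriC: forward strand on the right replichore, reverse
        # strand on the left
        if (right_rep[k]) fwd[bin_idx[k]] <- fwd[bin_idx[k]] + reads
        else rev_[bin_idx[k]] <- rev_[bin_idx[k]] + reads
      } else {
        fwd[bin_idx[k]] <- fwd[bin_idx[k]] + rpois(1, truth$depth / 2)
        rev_[bin_idx[k]] <- rev_[bin_idx[k]] + rpois(1, truth$depth / 2)
      }
    }
    if (truth$noise > 0) {
      fwd <- fwd + rpois(n, truth$noise)
      rev_ <- rev_ + rpois(n, truth$noise)
    }
  })
  coverage_track(bins$start, cbind(fwd = fwd, rev = rev_), bin_width,
                 genome$length, units = "raw")
}
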