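#' Detect peaks in a DNA-content intensity distribution
#'
#' Estimates a Gaussian-kernel density of per-event DAPI intensities on a
#' fixed grid and reports the grid points where the first derivative crosses
#' from positive to negative (equivalently, local maxima where the second
#' derivative is negative), filtered by topographic prominence.
#'
#' @param values Per-event fluorescence intensities (AU, >= 100 events).
#' @param bandwidth Kernel bandwidth in AU; default Silverman's rule
#'   (`stats::bw.nrd0`).
#' @param min_prominence Minimum peak prominence as a fraction of the maximum
#'   density (default 0.05, suppressing noise shoulders).
#' @param n_grid Density grid size.
#' @return List of class `peak_set` with `positions` (AU, ascending),
#'   `prominences`, `density` (the grid density as a data.frame).
#' @export
detect_peaks <- function(values, bandwidth = NULL, min_prominence = 0.05,
                         n_grid = 2048) {
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  if (length(values) < 100) stop("need >= 100 events", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be > 0", call. = FALSE)
  }
  d <- density(values, bw = bandwidth, n = n_grid)
  y <- d$y
  dy <- diff(y)
  # + to - crossing of the first derivative; interior points only
  is_peak <- which(dy[-length(dy)] > 0 & dy[-1] <= 0) + 1L
  prom <- vapply(is_peak, function(i) peak_prominence(y, i), 0)
  keep <- prom >= min_prominence * max(y)
  structure(
    list(positions = d$x[is_peak[keep]], prominences = prom[keep],
         density = data.frame(x = d$x, y = y), bandwidth = bandwidth),
    class = "peak_set"
  )
}

# Topographic prominence: on each side walk to the nearest higher point (or
# the boundary), record the minimum en route; the base is the higher of the
# two minima.
peak_prominence <- function(y, i) {
  left <- y[seq_len(i - 1)]
  right <- y[seq.int(i + 1, length(y))]
  higher_l <- which(left > y[i])
  higher_r <- which(right > y[i])
  min_l <- if (length(higher_l)) min(left[seq.int(max(higher_l), length(left))])
           else min(left)
  min_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))])
           else min(right)
  y[i] - max(min_l, min_r)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set>", length(x$positions), "peaks at",
      paste(sprintf("%.4g", x$positions), collapse = ", "), "\n")
  invisible(x)
}

#' Calibrate DAPI signal to chromosome number
#'
#' Least-squares line `signal = slope * count + intercept` through control
#' peak positions with assigned integer chromosome numbers (as plotted in
#' run-out calibrations), inverted for conversion.
#'
#' @param peak_positions Peak positions (AU).
#' @param assigned_counts Chromosome numbers assigned to each peak
#'   (distinct integers).
#' @return List of class `chromosome_calibration` with `slope`, `intercept`,
#'   `r2`.
#' @export
fit_chromosome_calibration <- function(peak_positions, assigned_counts) {
  stopifnot(length(peak_positions) == length(assigned_counts),
            length(peak_positions) >= 2)
  if (length(unique(assigned_counts)) < 2) {
    stop("assigned chromosome counts must be distinct", call. = FALSE)
  }
  fit <- lm(peak_positions ~ assigned_counts)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive", call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((peak_positions - mean(peak_positions))^2)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]), r2 = r2),
            class = "chromosome_calibration")
}

#' Convert DAPI signal to chromosome number
#'
#' @param calibration A [fit_chromosome_calibration()] result.
#' @param signal Intensities (AU).
#' @return Estimated chromosome numbers (real-valued).
#' @export
signal_to_chromosomes <- function(calibration, signal) {
  stopifnot(inherits(calibration, "chromosome_calibration"))
  (signal - calibration$intercept) / calibration$slope
}

#' Fraction of events at target chromosome numbers
#'
#' Converts each event's intensity to a chromosome estimate and reports, per
#' target `n`, the fraction of all events with `|estimate - n| <= tolerance`.
#'
#' @param values Per-event intensities (AU).
#' @param calibration A [fit_chromosome_calibration()] result.
#' @param targets Integer chromosome numbers.
#' @param tolerance Assignment half-width in chromosomes; must be < 0.5 so
#'   neighbouring integers stay unambiguous (default 0.35).
#' @return Named numeric vector of fractions (denominator = all events).
#' @export
chromosome_fractions <- function(values, calibration, targets,
                                 tolerance = 0.35) {
  stopifnot(is.numeric(values), length(values) > 0)
  if (tolerance >= 0.5) stop("tolerance >= 0.5 makes assignment ambiguous",
                             call. = FALSE)
  est <- signal_to_chromosomes(calibration, values)
  out <- vapply(targets, function(n) mean(abs(est - n) <= tolerance), 0)
  setNames(out, as.character(targets))
}

#' Normalize bulk fluorescence-reporter measurements
#'
#' Background-subtracts OD and fluorescence, forms fluorescence per OD, and
#' scales everything to the mean of the untreated samples.
#'
#' @param measurements Data.frame with columns `sample_id`, `od600`, `fluor`,
#'   `od_blank`, `fluor_blank`.
#' @param untreated_ids Sample ids defining the reference group.
#' @return The input with a `normalized_value` column appended.
#' @export
reporter_bulk_normalize <- function(measurements, untreated_ids) {
  need <- c("sample_id", "od600", "fluor", "od_blank", "fluor_blank")
  stopifnot(all(need %in% names(measurements)), length(untreated_ids) >= 1)
  od <- measurements$od600 - measurements$od_blank
  if (any(od <= 0)) {
    stop("od600 <= od_blank for sample(s): ",
         paste(measurements$sample_id[od <= 0], collapse = ", "), call. = FALSE)
  }
  per_od <- (measurements$fluor - measurements$fluor_blank) / od
  ref <- mean(per_od[measurements$sample_id %in% untreated_ids])
  if (!is.finite(ref) || ref == 0) stop("untreated reference mean is invalid",
                                        call. = FALSE)
  measurements$normalized_value <- per_od / ref
  measurements
}

#' Percent survival from selective vs titer plating
#'
#' `100 * (selective cfu/ml) / (titer cfu/ml)`, with cfu/ml reconstructed from
#' colony count, dilution fold, and plated volume.
#'
#' @param selective_count,titer_count Colony counts.
#' @param selective_dilution,titer_dilution Dilution folds (>= 1).
#' @param selective_volume,titer_volume Plated volumes (ml).
#' @return Percent survival.
#' @export
plating_viability <- function(selective_count, titer_count,
                              selective_dilution = 1, titer_dilution = 1,
                              selective_volume = 0.1, titer_volume = 0.1) {
  stopifnot(all(selective_count >= 0), all(selective_dilution >= 1),
            all(titer_dilution >= 1), all(selective_volume > 0),
            all(titer_volume > 0))
  if (any(titer_count <= 0)) stop("titer_count must be > 0", call. = FALSE)
  100 * (selective_count * selective_dilution / selective_volume) /
    (titer_count * titer_dilution / titer_volume)
}

#' Exponential-phase growth increment from a growth curve
#'
#' Difference of OD600 readings at 6.5 h and 5.5 h, using the nearest sampled
#' points; readings further than 7.5 min (half the usual 15-min cadence) from
#' a target time are an error.
#'
#' @param time Sampling times (hours).
#' @param od OD600 readings.
#' @param t_start,t_end Window endpoints in hours (defaults 5.5 and 6.5).
#' @return `od(t_end) - od(t_start)`.
#' @export
exponential_increment <- function(time, od, t_start = 5.5, t_end = 6.5) {
  stopifnot(length(time) == length(od), length(time) >= 2)
  pick <- function(t0) {
    i <- which.min(abs(time - t0))
    if (abs(time[i] - t0) > 0.125) {
      stop(sprintf("no OD reading within 7.5 min of t = %.2f h", t0),
           call. = FALSE)
    }
    od[i]
  }
  pick(t_end) - pick(t_start)
}
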