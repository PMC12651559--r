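#' Fixed-width coverage bins on a circular genome
#'
#' @param bin_starts Ascending 0-based bin starts tiling the circle once.
#' @param depth Per-bin depth: a numeric vector (unstranded) or a two-column
#'   matrix with columns `fwd` and `rev`.
#' @param bin_width Nominal bin width (the final bin may be shorter).
#' @param genome_length Chromosome length (bp).
#' @param units One of `"raw"`, `"cpm"`, `"cpm+terminus"`.
#' @param masked Logical per-bin mask flag.
#' @return List of class `coverage_track`.
#' @export
coverage_track <- function(bin_starts, depth, bin_width, genome_length,
                           units = "raw", masked = NULL) {
  stranded <- is.matrix(depth)
  n <- if (stranded) nrow(depth) else length(depth)
  stopifnot(length(bin_starts) == n, all(diff(bin_starts) > 0),
            bin_starts[1] == 0, genome_length > tail(bin_starts, 1))
  vals <- if (stranded) depth else matrix(depth, dimnames = list(NULL, NULL))
  stopifnot(all(is.finite(vals)), all(vals >= 0))
  if (stranded) stopifnot(identical(colnames(depth), c("fwd", "rev")))
  if (is.null(masked)) masked <- rep(FALSE, n)
  structure(
    list(bin_starts = bin_starts, depth = depth, bin_width = bin_width,
         genome_length = genome_length, stranded = stranded,
         units = units, normalized = units != "raw", masked = masked),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d bins x %d bp (%s%s), genome %.0f bp\n",
              length(x$bin_starts), x$bin_width, x$units,
              if (x$stranded) ", stranded" else "", x$genome_length))
  invisible(x)
}

make_bins <- function(genome_length, bin_width) {
  stopifnot(bin_width >= 1, genome_length >= bin_width)
  starts <- seq(0, genome_length - 1, by = bin_width)
  ends <- pmin(starts + bin_width, genome_length)
  if (genome_length %% bin_width != 0) {
    warning("bin_width does not divide the genome length; last bin shortened",
            call. = FALSE)
  }
  list(start = starts, end = ends)
}

track_values <- function(track) {
  if (track$stranded) rowSums(track$depth) else track$depth
}

bin_index_of <- function(track, pos) {
  pos <- wrap_coord(pos, track$genome_length)
  findInterval(pos, track$bin_starts)
}

#' Bin interval signal into fixed-width coverage bins
#'
#' Accumulates bedGraph-style interval signal (value treated as per-base
#' depth) into bins tiling the circular genome, length-weighting partial
#' overlaps; intervals may wrap past the coordinate origin. Masked genome
#' intervals are zeroed and flagged.
#'
#' @param intervals Data.frame with columns `start`, `end` (0-based
#'   half-open), `value`, and optionally `strand` (`"+"`/`"-"`), or a path
#'   to a bedGraph file (see [read_bedgraph()]); for stranded input, a list
#'   `list(fwd = , rev = )` of either.
#' @param genome A [genome_map()].
#' @param bin_width Bin width in bp (default 1000, the conventional 1 kb).
#' @param stranded Build a two-strand track.
#' @return A [coverage_track()] with `units = "raw"`.
#' @export
bin_coverage <- function(intervals, genome, bin_width = 1000,
                         stranded = FALSE) {
  stopifnot(inherits(genome, "genome_map"))
  bins <- make_bins(genome$length, bin_width)
  n <- length(bins$start)
  load_df <- function(x) {
    if (is.character(x)) x <- read_bedgraph(x)
    stopifnot(all(c("start", "end", "value") %in% names(x)))
    x
  }
  if (stranded) {
    if (is.list(intervals) && !is.data.frame(intervals) &&
        all(c("fwd", "rev") %in% names(intervals))) {
      fwd <- load_df(intervals$fwd)
      rev_ <- load_df(intervals$rev)
    } else {
      df <- load_df(intervals)
      stopifnot("strand" %in% names(df))
      fwd <- df[df$strand == "+", ]
      rev_ <- df[df$strand == "-", ]
    }
    depth <- cbind(fwd = accumulate_bins(fwd, bins, genome$length),
                   rev = accumulate_bins(rev_, bins, genome$length))
  } else {
    depth <- accumulate_bins(load_df(intervals), bins, genome$length)
  }
  masked <- rep(FALSE, n)
  for (iv in genome$masked_intervals) {
    masked <- masked | bins_overlap(bins, iv, genome$length)
  }
  if (any(masked)) {
    if (is.matrix(depth)) depth[masked, ] <- 0 else depth[masked] <- 0
  }
  coverage_track(bins$start, depth, bin_width, genome$length,
                 units = "raw", masked = masked)
}

accumulate_bins <- function(df, bins, genome_length) {
  out <- numeric(length(bins$start))
  if (!nrow(df)) return(out)
  stopifnot(all(df$end > df$start), all(df$start >= 0),
            all(df$start < genome_length), all(is.finite(df$value)))
  # split wrapping intervals at the coordinate origin
  wraps <- df$end > genome_length
  if (any(wraps)) {
    tailpart <- df[wraps, ]
    tailpart$start <- 0
    tailpart$end <- df$end[wraps] - genome_length
    df$end[wraps] <- genome_length
    df <- rbind(df, tailpart)
  }
  w <- bins$end[1] - bins$start[1]
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]; v <- df$value[i]
    b0 <- findInterval(s, bins$start)
    b1 <- findInterval(e - 1e-9, bins$start)
    idx <- b0:b1
    ov <- pmin(e, bins$end[idx]) - pmax(s, bins$start[idx])
    out[idx] <- out[idx] + v * ov
  }
  out
}

bins_overlap <- function(bins, interval, genome_length) {
  s <- wrap_coord(interval[1], genome_length)
  e <- interval[2]
  if (e <= s) e <- e + genome_length  # wrapping mask
  hit <- bins$start < e & bins$end > s
  if (e > genome_length) {
    hit <- hit | (bins$start < e - genome_length)
  }
  hit
}

#' Normalize a coverage track
#'
#' `"cpm"` scales bin depths to counts per million (total over all bins and
#' strands = 1e6); `"cpm+terminus"` additionally divides by the mean CPM over
#' the terminus window, correcting for terminus copy number so terminus
#' bins average 1.
#'
#' @param track A [coverage_track()].
#' @param genome A [genome_map()] (needed for the terminus window).
#' @param mode `"cpm"` or `"cpm+terminus"`.
#' @return A normalized [coverage_track()].
#' @export
normalize_track <- function(track, genome = NULL,
                            mode = c("cpm", "cpm+terminus")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "coverage_track"))
  total <- sum(track_values(track)[!track$masked])
  if (total <= 0) stop("total depth is zero", call. = FALSE)
  scale_to <- function(d, f) d * f
  if (track$units == "cpm" && mode == "cpm") return(track)  # idempotent
  d <- track$depth
  if (track$units == "raw") d <- scale_to(d, 1e6 / total)
  out <- track
  out$depth <- d
  out$units <- "cpm"
  if (mode == "cpm+terminus") {
    stopifnot(inherits(genome, "genome_map"))
    tw <- genome$terminus_window
    sel <- bins_overlap(list(start = track$bin_starts,
                             end = c(track$bin_starts[-1], track$genome_length)),
                        tw, track$genome_length) & !track$masked
    ter <- mean(track_values(out)[sel])
    if (!length(which(sel)) || !is.finite(ter) || ter <= 0) {
      stop("terminus window is masked or has zero depth", call. = FALSE)
    }
    out$depth <- out$depth / ter
    out$units <- "cpm+terminus"
  }
  out$normalized <- TRUE
  out
}

#' Average, outlier-trim, and smooth replicate coverage tracks
#'
#' Replicate tracks are averaged per bin; bins deviating more than `trim_k`
#' robust standard deviations (MAD) from a circular rolling median are
#' removed and imputed from their neighbours; the result is smoothed with a
#' locally weighted degree-1 regression (loess) with circular wrap.
#'
#' @param tracks A [coverage_track()] or list of replicate tracks on the same
#'   bins.
#' @param span Loess span as a fraction of the genome, in `(0, 0.5]`.
#' @param trim_k Outlier threshold in robust SDs (default 5).
#' @param trim_window Rolling-median window (bins, odd).
#' @return A smoothed [coverage_track()].
#' @export
smooth_and_trim <- function(tracks, span = 0.02, trim_k = 5,
                            trim_window = 25) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1, span > 0, span <= 0.5, trim_k > 0)
  t0 <- tracks[[1]]
  vals <- rowMeans(do.call(cbind, lapply(tracks, track_values)))
  n <- length(vals)
  rm_ <- circular_rolling_median(vals, trim_window)
  dev <- abs(vals - rm_)
  sigma <- mad(vals - rm_)
  if (sigma == 0) sigma <- sd(vals - rm_)  # isolated spikes on flat tracks
  bad <- if (sigma > 0) dev > trim_k * sigma else rep(FALSE, n)
  if (all(bad)) stop("all bins trimmed", call. = FALSE)
  vals[bad] <- rm_[bad]  # impute from the local neighbourhood median
  # circular loess: pad with a guard band of one span on each side
  pad <- ceiling(span * n) + 1
  idx <- c((n - pad + 1):n, 1:n, 1:pad)
  x <- seq_along(idx)
  fit <- loess(vals[idx] ~ x, span = span * n / length(idx), degree = 1,
               family = "gaussian", surface = "direct")
  sm <- predict(fit)[(pad + 1):(pad + n)]
  out <- t0
  out$depth <- pmax(sm, 0)
  out$stranded <- FALSE
  out
}

circular_rolling_median <- function(x, k) {
  k <- max(3L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(x)
  h <- (k - 1L) %/% 2L
  xp <- c(tail(x, h), x, head(x, h))
  vapply(seq_len(n), function(i) median(xp[i:(i + k - 1L)]), 0)
}

#' Replicore asymmetry at a locus
#'
#' Depth at the locus bin divided by depth at the mirror bin -- the point on
#' the sister replichore at equal circular distance from *oriC*. By
#' construction `asymmetry(locus) * asymmetry(mirror(locus)) = 1`.
#'
#' @param track A [coverage_track()].
#' @param genome A [genome_map()].
#' @param locus Coordinate (bp) or the name of a genome locus.
#' @return The depth ratio (NA with a warning if either bin is masked).
#' @export
replicore_asymmetry <- function(track, genome, locus) {
  stopifnot(inherits(track, "coverage_track"), inherits(genome, "genome_map"))
  if (is.character(locus)) locus <- genome$loci[[locus]]
  if (wrap_coord(locus, genome$length) == genome$oric) {
    stop("locus coincides with oriC", call. = FALSE)
  }
  i <- bin_index_of(track, locus)
  j <- bin_index_of(track, mirror_locus(genome, locus))
  if (track$masked[i] || track$masked[j]) {
    warning("locus or mirror bin is masked; asymmetry undefined", call. = FALSE)
    return(NA_real_)
  }
  v <- track_values(track)
  v[i] / v[j]
}

#' Detect degradation plateaus in a coverage profile
#'
#' Finds maximal runs of consecutive bins whose per-bin relative slope (on a
#' circular rolling median, which preserves step edges) stays within
#' `flatness_tol`, keeps runs of at least `min_length` bins whose level lies
#' below the linear trend fitted through the flanking windows, and refines
#' each boundary to the half-height crossing on the raw track. Because a
#' degradation tract by mechanism runs from the rear-end site through *oriC*
#' to the sister replichore, only runs containing the origin are reported
#' (disable with `require_oric = FALSE`); runs covering over 90% of the
#' genome (e.g. a fully flat completed-run-out profile) are never plateaus.
#'
#' @param track A normalized (and at most lightly smoothed)
#'   [coverage_track()].
#' @param genome A [genome_map()].
#' @param min_length Minimum run length in bins.
#' @param flatness_tol Maximum per-bin relative change within a run.
#' @param depth_margin Required relative depression below the flanking trend
#'   (default 0.1).
#' @param require_oric Only report runs containing the *oriC* bin (default
#'   `TRUE`).
#' @return Data.frame with columns `start`, `end` (bp, half-open, `end` may
#'   exceed the genome length for plateaus wrapping the coordinate origin)
#'   and `level`; zero rows if no plateau.
#' @export
detect_degradation_plateau <- function(track, genome, min_length = 50,
                                       flatness_tol = 0.1,
                                       depth_margin = 0.1,
                                       require_oric = TRUE) {
  stopifnot(inherits(track, "coverage_track"), min_length >= 2,
            flatness_tol > 0)
  oric_bin <- bin_index_of(track, genome$oric)
  v <- track_values(track)
  n <- length(v)
  # wide rolling median stabilizes run detection under sampling noise; the
  # raw-track half-height refinement below restores sharp boundaries
  rm_ <- circular_rolling_median(v, 21)
  lvl <- pmax((rm_ + c(rm_[-1], rm_[1])) / 2, 1e-12)
  flat_edge <- abs(c(rm_[-1], rm_[1]) - rm_) / lvl <= flatness_tol  # edge i: i -> i+1
  runs <- circular_runs(flat_edge)
  out <- list()
  for (r in runs) {
    len <- length(r)
    if (len < min_length || len > 0.9 * n) next
    if (require_oric && !(oric_bin %in% r)) next
    fl <- min(len, 50)
    left_fl <- ((r[1] - fl - 1):(r[1] - 2)) %% n + 1
    right_fl <- ((r[len]):(r[len] + fl - 1)) %% n + 1
    # extrapolate each flank's linear trend across the run separately, so a
    # truncated pyramid apex (slopes rising toward the run on both sides) is
    # recognized; the reference is the mean of the two extrapolations. The
    # slope is used only when statistically clear, and the extrapolation is
    # frozen beyond a few flank lengths so noise does not compound over
    # long runs.
    pred_l <- flank_extrapolation(rm_[left_fl], seq_len(fl) - fl - 1,
                                  pmin(seq_len(len), 4 * fl))
    pred_r <- flank_extrapolation(rm_[right_fl], len + seq_len(fl),
                                  pmax(seq_len(len), len - 4 * fl))
    pred <- (pred_l + pred_r) / 2
    run_level <- mean(rm_[r])
    if (!(run_level < (1 - depth_margin) * mean(pred))) next
    # refine boundaries: half-height crossing on the raw track
    thr_l <- (median(rm_[left_fl]) + run_level) / 2
    thr_r <- (median(rm_[right_fl]) + run_level) / 2
    b_l <- refine_boundary(v, r[1], thr_l, n, dir = -1)
    b_r <- refine_boundary(v, r[len], thr_r, n, dir = +1)
    start_bp <- track$bin_starts[b_l]
    end_bp <- track$bin_starts[b_r] + track$bin_width
    if (end_bp <= start_bp) end_bp <- end_bp + track$genome_length
    out[[length(out) + 1]] <- data.frame(start = start_bp, end = end_bp,
                                         level = run_level)
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      level = numeric(0)))
  }
  do.call(rbind, out)
}

flank_extrapolation <- function(ys, xs, at) {
  fit <- lm(ys ~ xs)
  sl <- coef(summary(fit))
  slope <- if (nrow(sl) > 1 && is.finite(sl[2, 3]) && abs(sl[2, 3]) >= 2) {
    sl[2, 1]
  } else 0
  mean(ys) + slope * (at - mean(xs))
}

# walk outwards from a run end while raw values stay below the threshold
refine_boundary <- function(v, i, thr, n, dir, max_step = 30) {
  if (v[i] > thr) {
    # run edge overshot the step (median blur): walk inwards to the crossing
    for (step in 1:max_step) {
      j <- (i - dir * step - 1) %% n + 1
      if (v[j] <= thr) return(j)
    }
    return(i)
  }
  for (step in 1:max_step) {
    j <- (i + dir * step - 1) %% n + 1
    if (v[j] > thr) return((i + dir * (step - 1) - 1) %% n + 1)
  }
  i
}

# maximal circular runs of TRUE edges, returned as bin index vectors
# (edge i connects bin i to bin i+1; a run of edges i..j spans bins i..j+1)
circular_runs <- function(flat_edge) {
  n <- length(flat_edge)
  if (all(flat_edge)) return(list(seq_len(n)))
  if (!any(flat_edge)) return(list())
  # rotate so position 1 is not flat
  off <- which(!flat_edge)[1]
  rot <- flat_edge[((seq_len(n) + off - 2) %% n) + 1]
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    idx <- (starts[k]:(ends[k] + 1))  # edges i..j cover bins i..j+1
    runs[[length(runs) + 1]] <- ((idx + off - 2) %% n) + 1
  }
  runs
}

#' Strand orientation index of a stranded end-signal track
#'
#' Per bin, `oi = (R - L)/(R + L)` with `R` the forward ("right-facing") and
#' `L` the reverse strand signal. The genome-wide `away_fraction` is the
#' share of signal oriented away from *oriC* along its replichore:
#' right-facing on the right replichore, left-facing on the left.
#'
#' @param track A stranded [coverage_track()].
#' @param genome A [genome_map()].
#' @return List of class `orientation_track`: `oi` (per bin, NA where
#'   `R + L = 0`), `away_fraction`, `bin_starts`.
#' @export
orientation_index <- function(track, genome) {
  stopifnot(inherits(track, "coverage_track"), track$stranded,
            inherits(genome, "genome_map"))
  R <- track$depth[, "fwd"]
  L <- track$depth[, "rev"]
  tot <- R + L
  if (sum(tot) == 0) stop("track has no signal", call. = FALSE)
  oi <- ifelse(tot > 0, (R - L) / tot, NA_real_)
  mids <- track$bin_starts + track$bin_width / 2
  right_rep <- replichore_position(genome, mids)$replichore == "right"
  away <- sum(R[right_rep]) + sum(L[!right_rep])
  structure(list(oi = oi, away_fraction = away / sum(tot),
                 bin_starts = track$bin_starts),
            class = "orientation_track")
}

#' Origin-to-terminus coverage ratio
#'
#' Mean depth in a window around *oriC* divided by the mean depth in a window
#' around the terminus point; `2^n` for `n` overlapping fork generations in
#' exponential phase, ~1 after a completed run-out.
#'
#' @param track A [coverage_track()].
#' @param genome A [genome_map()].
#' @param window Window half-width (bp) on each side of the two points.
#' @return The depth ratio.
#' @export
origin_terminus_ratio <- function(track, genome, window = 20000) {
  stopifnot(inherits(track, "coverage_track"), inherits(genome, "genome_map"))
  v <- track_values(track)
  ter <- wrap_coord(genome$oric + genome$length / 2, genome$length)
  sel <- function(center) {
    d <- circ_dist(track$bin_starts + track$bin_width / 2, center,
                   genome$length)
    which(d <= window & !track$masked)
  }
  ori_bins <- sel(genome$oric)
  ter_bins <- sel(ter)
  if (!length(ori_bins) || !length(ter_bins)) {
    stop("origin or terminus window is fully masked", call. = FALSE)
  }
  ter_mean <- mean(v[ter_bins])
  if (ter_mean <= 0) stop("zero terminus depth", call. = FALSE)
  mean(v[ori_bins]) / ter_mean
}
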