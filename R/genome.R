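#' Describe a circular bacterial chromosome
#'
#' A `genome_map` carries the reference frame every coverage computation uses:
#' chromosome length, the replication origin (*oriC*), a terminus window used
#' for copy-number normalization, optional masked intervals, and named loci
#' (for example a head-on rRNA collision locus). Coordinates are 0-based,
#' half-open, and wrap at `length`.
#'
#' The two replichores are defined relative to *oriC*: the "right" replichore
#' runs clockwise (increasing coordinates, wrapping) from *oriC* to the point
#' diametrically opposite; the "left" replichore runs counterclockwise.
#'
#' @param length Chromosome length in bp (> 0).
#' @param oric 0-based coordinate of the replication origin.
#' @param terminus_window Integer vector `c(start, end)`, 0-based half-open,
#'   the window treated as terminus for normalization. Defaults to +/- 100 kb
#'   around the point opposite *oriC*.
#' @param masked_intervals List of `c(start, end)` half-open intervals to
#'   exclude from analysis (e.g. an END-seq terminus mask).
#' @param loci Named numeric vector of marker coordinates.
#' @return An object of class `genome_map`.
#' @examples
#' gm <- genome_map(length = 1e6, oric = 0)
#' mirror_locus(gm, 2.5e5)
#' @export
genome_map <- function(length, oric, terminus_window = NULL,
                       masked_intervals = list(), loci = c()) {
  stopifnot(is.numeric(length), length > 0, is.numeric(oric))
  length <- as.numeric(length)
  oric <- wrap_coord(as.numeric(oric), length)
  if (is.null(terminus_window)) {
    ter <- wrap_coord(oric + length / 2, length)
    half <- min(1e5, length / 10)
    terminus_window <- c(wrap_coord(ter - half, length),
                         wrap_coord(ter + half, length))
  }
  stopifnot(length(terminus_window) == 2L)
  for (iv in masked_intervals) stopifnot(length(iv) == 2L)
  if (length(loci)) {
    stopifnot(!is.null(names(loci)), all(loci >= 0), all(loci < length))
  }
  structure(
    list(length = length, oric = oric,
         terminus_window = as.numeric(terminus_window),
         masked_intervals = masked_intervals,
         loci = loci),
    class = "genome_map"
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %.0f bp circular, oriC at %.0f\n", x$length, x$oric))
  cat(sprintf("  terminus window: [%.0f, %.0f)\n",
              x$terminus_window[1], x$terminus_window[2]))
  if (length(x$loci))
    cat("  loci:", paste(sprintf("%s=%.0f", names(x$loci), x$loci),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Signed origin distance and replichore of a coordinate
#'
#' Positions are expressed as a fraction of a replichore (half the circle):
#' 0 at *oriC*, 1 at the terminus point opposite it. The replichore is
#' `"right"` for clockwise (increasing-coordinate) positions.
#'
#' @param genome A [genome_map()].
#' @param pos Coordinates (bp).
#' @return A data.frame with columns `fraction` and `replichore`.
#' @export
replichore_position <- function(genome, pos) {
  stopifnot(inherits(genome, "genome_map"))
  half <- genome$length / 2
  d <- wrap_coord(pos - genome$oric, genome$length)  # clockwise distance
  right <- d <= half
  data.frame(
    fraction = ifelse(right, d / half, (genome$length - d) / half),
    replichore = ifelse(right, "right", "left"),
    stringsAsFactors = FALSE
  )
}

#' Coordinate of a replichore fraction
#'
#' Inverse of [replichore_position()].
#'
#' @param genome A [genome_map()].
#' @param fraction Fraction of the replichore in `[0, 1]`.
#' @param replichore `"right"` or `"left"`.
#' @return Coordinates in bp.
#' @export
replichore_coord <- function(genome, fraction, replichore) {
  stopifnot(inherits(genome, "genome_map"), all(fraction >= 0), all(fraction <= 1))
  half <- genome$length / 2
  sgn <- ifelse(replichore == "right", 1, -1)
  wrap_coord(genome$oric + sgn * fraction * half, genome$length)
}

#' Mirror a locus onto the sister replichore
#'
#' Returns the coordinate on the other replichore at equal circular distance
#' from *oriC*.
#'
#' @param genome A [genome_map()].
#' @param pos Coordinate (bp).
#' @return Mirrored coordinate (bp).
#' @export
mirror_locus <- function(genome, pos) {
  stopifnot(inherits(genome, "genome_map"))
  wrap_coord(2 * genome$oric - pos, genome$length)
}

#' Reference frame for the E. coli K-12 MG1655 chromosome
#'
#' Default coordinates for the NC_000913.3 assembly, read from the plain-text
#' config shipped with the package; every field can be overridden, and no
#' coordinate constant is hard-coded in analysis logic.
#'
#' @param config Path to a key-value config file; defaults to the packaged one.
#' @return A [genome_map()].
#' @export
genome_NC000913 <- function(config = system.file("extdata", "NC_000913.3.conf",
                                                 package = "replireset")) {
  kv <- read_genome_config(config)
  genome_map(
    length = kv$length, oric = kv$oric,
    terminus_window = c(kv$terminus_start, kv$terminus_end),
    loci = c(invD = kv$invD)
  )
}

read_genome_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\\s*[=:]\\s*")
  vals <- lapply(parts, function(p) as.numeric(p[2]))
  names(vals) <- vapply(parts, `[`, "", 1)
  vals
}
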