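#' Read and write bedGraph files
#'
#' Four-column bedGraph (chrom, start, end, value), 0-based half-open,
#' via rtracklayer. Stranded tracks are written as one file per strand.
#'
#' @param track A [coverage_track()] (for writing).
#' @param path Output path; for a stranded track, a vector
#'   `c(fwd = , rev = )`.
#' @param chrom Chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  stopifnot(inherits(track, "coverage_track"))
  ends <- c(track$bin_starts[-1], track$genome_length)
  gr_of <- function(vals) {
    GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = track$bin_starts + 1, end = ends),
      score = as.numeric(vals),
      seqlengths = stats::setNames(as.integer(track$genome_length), chrom)
    )
  }
  if (track$stranded) {
    stopifnot(all(c("fwd", "rev") %in% names(path)))
    rtracklayer::export(gr_of(track$depth[, "fwd"]), path[["fwd"]],
                        format = "bedGraph")
    rtracklayer::export(gr_of(track$depth[, "rev"]), path[["rev"]],
                        format = "bedGraph")
  } else {
    rtracklayer::export(gr_of(track$depth), path[[1]], format = "bedGraph")
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score)
}

#' Read a bedGraph pair (or interval data) into a coverage track
#'
#' Convenience wrapper: reads one file (unstranded) or a fwd/rev pair and
#' bins it on the genome.
#'
#' @param path File path, or `c(fwd = , rev = )` for stranded data.
#' @param genome A [genome_map()].
#' @param bin_width Bin width in bp.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, genome, bin_width = 1000) {
  if (length(path) == 2 && all(c("fwd", "rev") %in% names(path))) {
    bin_coverage(list(fwd = read_bedgraph(path[["fwd"]]),
                      rev = read_bedgraph(path[["rev"]])),
                 genome, bin_width, stranded = TRUE)
  } else {
    bin_coverage(read_bedgraph(path), genome, bin_width)
  }
}

#' Write / read a single-column intensity CSV
#'
#' @param values Per-event intensities.
#' @param path File path.
#' @export
write_intensities <- function(values, path) {
  write.table(data.frame(intensity = values), path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  read.table(path, sep = ",", header = TRUE)$intensity
}

#' Write a truth record as a key-value sidecar
#'
#' Scalar fields of a generator truth object, one `key = value` per line,
#' for round-trip provenance next to simulated data files.
#'
#' @param truth Any truth object (a list of mostly scalar fields).
#' @param path Output path.
#' @export
write_truth_sidecar <- function(truth, path) {
  flat <- truth[vapply(truth, function(x)
    is.atomic(x) && length(x) == 1 && !is.na(x), TRUE)]
  writeLines(sprintf("%s = %s", names(flat),
                     vapply(flat, format, "", digits = 15)), path)
  invisible(path)
}
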