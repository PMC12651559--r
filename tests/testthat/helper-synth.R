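# Shared fixtures, all generated in code.

write_test_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)), reads, "+",
                           vapply(reads, function(r) strrep("I", nchar(r)), "")))
  writeLines(lines, path)
  path
}

toy_guide_library <- function() {
  data.frame(
    guide_id = c("gA_1", "gB_1", "gC_1"),
    sequence = c(strrep("A", 20), strrep("C", 20),
                 paste0(strrep("G", 10), strrep("T", 10))),
    gene = c("gA", "gB", "gC"),
    stringsAsFactors = FALSE
  )
}

toy_genome <- function(length = 10000, oric = 0, ...) {
  genome_map(length = length, oric = oric, ...)
}

# coverage track straight from per-bin values
track_from_values <- function(values, genome, bin_width = NULL,
                              units = "raw") {
  if (is.null(bin_width)) bin_width <- genome$length / NROW(values)
  coverage_track(bin_starts = seq(0, genome$length - 1, by = bin_width),
                 depth = values, bin_width = bin_width,
                 genome_length = genome$length, units = units)
}

# steady-state age-structure survival: P(round j fraction >= f), the
# closed-form oracle for exponential-phase copy number
age_survival <- function(t) ifelse(t <= 0, 1, ifelse(t >= 1, 0, 2^(1 - t) - 1))

expected_exponential_copy <- function(fraction, G) {
  out <- rep(1, length(fraction))
  for (j in seq_len(G)) {
    out <- out + 2^(j - 1) * age_survival(G * fraction - (G - j))
  }
  out
}
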