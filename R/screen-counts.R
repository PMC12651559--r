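#' Guide-by-sample count matrix
#'
#' Container for sgRNA count tables. Sample names follow
#' `<condition>_<timepoint>_<replicate>` with timepoint `pre` (before dCas9
#' induction) or `post` (after outgrowth); conditions may themselves contain
#' underscores, the two final fields are parsed from the right.
#'
#' @param counts Non-negative integer matrix, guides in rows (rownames =
#'   guide ids), samples in columns.
#' @param gene Character vector mapping each guide to exactly one gene.
#' @param unmatched_reads Optional per-sample count of unassigned reads.
#' @return List of class `count_matrix` with `counts`, `gene`, `samples`
#'   (data.frame: sample, condition, timepoint, replicate), `unmatched_reads`.
#' @export
count_matrix <- function(counts, gene, unmatched_reads = NULL) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0), all(is.finite(counts)),
            all(counts == round(counts)))
  if (is.null(rownames(counts))) stop("counts must have guide ids as rownames")
  stopifnot(!anyDuplicated(rownames(counts)), length(gene) == nrow(counts))
  samples <- parse_sample_names(colnames(counts))
  if (!is.null(unmatched_reads)) {
    stopifnot(length(unmatched_reads) == ncol(counts))
  }
  structure(list(counts = counts, gene = as.character(gene), samples = samples,
                 unmatched_reads = unmatched_reads),
            class = "count_matrix")
}

parse_sample_names <- function(x) {
  stopifnot(!is.null(x), !anyDuplicated(x))
  parts <- strsplit(x, "_")
  bad <- vapply(parts, length, 0L) < 3L
  if (any(bad)) {
    stop("sample names must be <condition>_<pre|post>_<replicate>: ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  rep_ <- vapply(parts, function(p) p[length(p)], "")
  tp <- vapply(parts, function(p) p[length(p) - 1L], "")
  cond <- vapply(parts, function(p) paste(p[-c(length(p) - 1L, length(p))],
                                          collapse = "_"), "")
  stopifnot(all(tp %in% c("pre", "post")))
  data.frame(sample = x, condition = cond, timepoint = tp, replicate = rep_,
             stringsAsFactors = FALSE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d guides x %d samples, %d genes\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gene))))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' Columns: `guide_id`, `gene`, then one column per sample.
#'
#' @param x A [count_matrix()].
#' @param path Output file.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(guide_id = rownames(x$counts), gene = x$gene,
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("guide_id", "gene")), drop = FALSE])
  rownames(counts) <- df$guide_id
  count_matrix(counts, gene = df$gene)
}

#' Count exact guide matches in a FASTQ file
#'
#' Reproduces the screen's read-to-guide assignment: a read is counted for a
#' guide if and only if its first 20 nt exactly equal the guide sequence
#' (reads are sequenced as single-end 20 bp, so no overhang is required).
#' Each read increments exactly one guide or the unmatched tally.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param library Data.frame with columns `guide_id`, `sequence` (20-nt,
#'   unique), `gene`.
#' @return List with `counts` (named per guide), `unmatched`, `n_reads`.
#' @export
count_guides <- function(fastq, library) {
  stopifnot(all(c("guide_id", "sequence", "gene") %in% names(library)))
  seqs <- toupper(library$sequence)
  if (anyDuplicated(seqs)) stop("duplicate library sequences", call. = FALSE)
  if (!all(nchar(seqs) == 20L) || !all(grepl("^[ACGT]+$", seqs))) {
    stop("library sequences must be 20-nt ACGT strings", call. = FALSE)
  }
  reads <- read_fastq_sequences(fastq)
  n_reads <- length(reads)
  counts <- setNames(integer(length(seqs)), library$guide_id)
  unmatched <- 0L
  if (n_reads > 0) {
    keys <- substr(reads, 1L, 20L)
    keys[nchar(reads) < 20L] <- NA_character_  # short reads never match
    idx <- match(keys, seqs)
    tab <- table(factor(idx, levels = seq_along(seqs)))
    counts[] <- as.integer(tab)
    unmatched <- n_reads - sum(counts)
  }
  list(counts = counts, unmatched = unmatched, n_reads = n_reads)
}

read_fastq_sequences <- function(path) {
  stopifnot(file.exists(path))
  n_lines <- length(readLines(path, n = 4L, warn = FALSE))
  if (n_lines == 0L) return(character(0))  # Biostrings rejects empty FASTQ
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
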