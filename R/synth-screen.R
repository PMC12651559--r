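#' Ground truth for a simulated CRISPRi fitness screen
#'
#' Describes a pooled guide library with gene-level fitness effects. Each
#' guide `i` targeting gene `g` grows, relative to neutral cells, by a factor
#' `2^(d * (1 + e_i * s_gc))` over `d` population doublings in condition `c`;
#' `s = 0` is neutral, `s = -1` a full knockdown of an essential gene
#' (no growth), `s > 0` an advantage.
#'
#' @param n_genes Number of genes.
#' @param guides_per_gene Guides per gene.
#' @param fitness_effect Matrix (`n_genes` x conditions) of per-doubling
#'   fitness effects `s`, or a named list of per-condition vectors. Values
#'   must be >= -1.
#' @param baseline_abundance Expected T0 fraction per guide (simplex);
#'   default slightly uneven abundances drawn deterministically.
#' @param guide_efficacy Per-guide efficacy in `[0, 1]`; default 1.
#' @param doublings Outgrowth length in population doublings.
#' @param dispersion NB overdispersion alpha (>= 0; 0 = Poisson).
#' @param library_size Reads per sample.
#' @return List of class `screen_truth`.
#' @export
screen_truth <- function(n_genes, guides_per_gene, fitness_effect,
                         baseline_abundance = NULL, guide_efficacy = NULL,
                         doublings = 10, dispersion = 0.05,
                         library_size = 1e7) {
  n_genes <- as.integer(n_genes)
  guides_per_gene <- as.integer(guides_per_gene)
  n_guides <- n_genes * guides_per_gene
  if (is.list(fitness_effect)) {
    fitness_effect <- do.call(cbind, fitness_effect)
  }
  if (is.null(dim(fitness_effect))) {
    fitness_effect <- matrix(fitness_effect, ncol = 1,
                             dimnames = list(NULL, "condition1"))
  }
  stopifnot(nrow(fitness_effect) == n_genes, all(fitness_effect >= -1),
            all(is.finite(fitness_effect)))
  if (is.null(colnames(fitness_effect))) {
    colnames(fitness_effect) <- paste0("condition", seq_len(ncol(fitness_effect)))
  }
  if (is.null(baseline_abundance)) {
    # mildly uneven library representation, fixed (not a random draw)
    w <- 1 + 0.5 * sin(seq_len(n_guides))
    baseline_abundance <- w / sum(w)
  }
  stopifnot(length(baseline_abundance) == n_guides, all(baseline_abundance > 0))
  baseline_abundance <- baseline_abundance / sum(baseline_abundance)
  if (is.null(guide_efficacy)) guide_efficacy <- rep(1, n_guides)
  stopifnot(length(guide_efficacy) == n_guides,
            all(guide_efficacy >= 0), all(guide_efficacy <= 1))
  stopifnot(is.finite(doublings), doublings >= 0)
  if (!is.numeric(dispersion) || dispersion < 0) {
    stop("`dispersion` must be >= 0", call. = FALSE)
  }
  stopifnot(library_size >= 1)
  structure(
    list(n_genes = n_genes, guides_per_gene = guides_per_gene,
         gene = rep(paste0("gene", seq_len(n_genes)), each = guides_per_gene),
         guide_id = paste0("gene", rep(seq_len(n_genes), each = guides_per_gene),
                           "_g", rep(seq_len(guides_per_gene), n_genes)),
         baseline_abundance = baseline_abundance,
         guide_efficacy = guide_efficacy,
         fitness_effect = fitness_effect,
         doublings = doublings, dispersion = dispersion,
         library_size = library_size),
    class = "screen_truth"
  )
}

#' Simulate paired pre/post induction guide count tables
#'
#' T0 (pre) counts are sampled around the baseline abundances; Tend (post)
#' expected fractions are the baseline fractions multiplied by
#' `2^(d (1 + e_i s_gc))` and renormalized, so a fully depleted gene
#' (`s = -1`, `e = 1`) falls `2^d`-fold behind neutral guides. Counts are
#' negative binomial with mean `fraction * library_size` and dispersion
#' `alpha` (Poisson when `alpha = 0`).
#'
#' @param truth A [screen_truth()].
#' @param n_replicates Replicates per condition and timepoint.
#' @param seed Integer seed.
#' @return A [count_matrix()] with samples `<condition>_<pre|post>_<rep>` for
#'   every condition in the truth.
#' @export
simulate_screen_counts <- function(truth, n_replicates, seed) {
  stopifnot(inherits(truth, "screen_truth"), n_replicates >= 1)
  n_replicates <- as.integer(n_replicates)
  conds <- colnames(truth$fitness_effect)
  n_guides <- length(truth$guide_id)

  growth_fraction <- function(cond) {
    s_guide <- truth$fitness_effect[match(truth$gene,
                                          paste0("gene", seq_len(truth$n_genes))),
                                    cond]
    expo <- truth$doublings * (1 + truth$guide_efficacy * s_guide)
    if (any(!is.finite(expo))) stop("non-finite growth exponent", call. = FALSE)
    f <- truth$baseline_abundance * 2^expo
    f / sum(f)
  }

  draw <- function(fraction) {
    mu <- fraction * truth$library_size
    if (truth$dispersion == 0) rpois(n_guides, mu)
    else rnbinom(n_guides, mu = mu, size = 1 / truth$dispersion)
  }

  counts <- with_seed(seed, {
    cols <- list()
    for (cond in conds) {
      f_end <- growth_fraction(cond)
      for (r in seq_len(n_replicates)) {
        cols[[paste(cond, "pre", r, sep = "_")]] <- draw(truth$baseline_abundance)
        cols[[paste(cond, "post", r, sep = "_")]] <- draw(f_end)
      }
    }
    do.call(cbind, cols)
  })
  rownames(counts) <- truth$guide_id
  count_matrix(counts, gene = truth$gene)
}
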