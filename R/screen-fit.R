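#' Median-of-ratios size factors
#'
#' Treats sgRNA counts like RNA-seq counts: each sample's factor is the median
#' across all-nonzero guides of the ratio of its count to the guide's
#' geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts A [count_matrix()] or a numeric matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    stop("no guide has nonzero counts in every sample; consider a ",
         "pseudo-reference (e.g. add a pseudocount) before size-factor ",
         "estimation", call. = FALSE)
  }
  logs <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(logs)
  sf <- apply(exp(logs - geo), 2, median)
  sf / exp(mean(log(sf)))
}

#' Normalized counts
#'
#' @param counts A [count_matrix()] or matrix.
#' @param size_factors Output of [estimate_size_factors()].
#' @return Matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(counts, size_factors = estimate_size_factors(counts)) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  sweep(m, 2, size_factors, "/")
}

#' Per-guide negative-binomial dispersions with a mean trend
#'
#' Method-of-moments dispersion per guide within each (condition, timepoint)
#' replicate group on normalized counts, `alpha_i = max(0, (s^2 - mu) / mu^2)`,
#' combined across groups by a df-weighted mean. A robust least-squares trend
#' `alpha(mu) = a0 + a1 / mu` is then fit over guides with positive raw
#' dispersion and evaluated at each guide's mean; the trend value is the final
#' dispersion (no empirical-Bayes shrinkage toward it -- a documented
#' simplification of the usual count-model machinery).
#'
#' @param counts A [count_matrix()].
#' @param size_factors Per-sample size factors.
#' @return List of class `normalization_model` with `size_factors`,
#'   `dispersions` (per guide, trend values), `dispersion_raw`,
#'   `trend_coefficients` (a0, a1), `base_mean`.
#' @export
estimate_dispersions <- function(counts, size_factors = estimate_size_factors(counts)) {
  stopifnot(inherits(counts, "count_matrix"))
  norm <- normalized_counts(counts, size_factors)
  groups <- interaction(counts$samples$condition, counts$samples$timepoint,
                        drop = TRUE)
  sizes <- table(groups)
  if (all(sizes < 2)) {
    stop("need >= 2 replicates in at least one (condition, timepoint) group",
         call. = FALSE)
  }
  num <- denom <- wsum <- numeric(nrow(norm))
  for (g in names(sizes)[sizes >= 2]) {
    sub <- norm[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    w <- ncol(sub) - 1
    ok <- mu > 0
    num[ok] <- num[ok] + w * (v[ok] - mu[ok]) / mu[ok]^2
    wsum[ok] <- wsum[ok] + w
  }
  alpha_raw <- ifelse(wsum > 0, pmax(0, num / pmax(wsum, 1)), NA_real_)
  base_mean <- rowMeans(norm)
  fit_on <- which(alpha_raw > 0 & base_mean > 0)
  if (length(fit_on) >= 10) {
    rf <- MASS::rlm(alpha_raw[fit_on] ~ I(1 / base_mean[fit_on]), maxit = 50)
    a <- coef(rf)
  } else {
    # too few informative guides for a trend: flat fallback at the median
    a <- c(median(alpha_raw[fit_on], na.rm = TRUE), 0)
    if (!is.finite(a[1])) a[1] <- 0
  }
  trend <- pmax(0, a[1] + a[2] / pmax(base_mean, 1e-8))
  structure(
    list(size_factors = size_factors, dispersions = trend,
         dispersion_raw = alpha_raw, trend_coefficients = setNames(a, c("a0", "a1")),
         base_mean = base_mean),
    class = "normalization_model"
  )
}

#' Per-guide log2 fold change post vs pre induction
#'
#' `lfc_i = log2((mean normalized post + c) / (mean normalized pre + c))` with
#' pseudocount `c` (default 0.5 normalized counts). The standard error uses
#' the delta method with NB variance `mu + alpha mu^2` on each sample mean.
#'
#' @param counts A [count_matrix()].
#' @param model A `normalization_model` from [estimate_dispersions()].
#' @param condition Condition whose pre/post samples are compared.
#' @param pseudocount Stabilizing constant added to both means.
#' @param low_coverage_threshold Guides with pre-induction normalized mean
#'   below this are flagged and excluded from gene aggregation (default 10).
#' @return Data.frame: `guide_id`, `gene`, `lfc`, `se`, `mean_pre`,
#'   `mean_post`, `low_coverage` (pre-induction normalized mean < threshold
#'   in the attribute `low_coverage_threshold`).
#' @export
guide_log2fc <- function(counts, model, condition, pseudocount = 0.5,
                         low_coverage_threshold = 10) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(model, "normalization_model"))
  s <- counts$samples
  pre <- s$sample[s$condition == condition & s$timepoint == "pre"]
  post <- s$sample[s$condition == condition & s$timepoint == "post"]
  if (!length(pre) || !length(post)) {
    stop(sprintf("condition '%s' needs both pre and post samples", condition),
         call. = FALSE)
  }
  norm <- normalized_counts(counts, model$size_factors)
  mu_pre <- rowMeans(norm[, pre, drop = FALSE])
  mu_post <- rowMeans(norm[, post, drop = FALSE])
  lfc <- log2((mu_post + pseudocount) / (mu_pre + pseudocount))
  alpha <- model$dispersions
  var_mean <- function(mu, n) (mu + alpha * mu^2) / n
  # delta method on log2 of each (mean + c)
  se <- sqrt(var_mean(mu_pre, length(pre)) / ((mu_pre + pseudocount) * log(2))^2 +
             var_mean(mu_post, length(post)) / ((mu_post + pseudocount) * log(2))^2)
  out <- data.frame(
    guide_id = rownames(counts$counts), gene = counts$gene,
    lfc = lfc, se = se, mean_pre = mu_pre, mean_post = mu_post,
    low_coverage = mu_pre < low_coverage_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "pseudocount") <- pseudocount
  attr(out, "low_coverage_threshold") <- low_coverage_threshold
  attr(out, "condition") <- condition
  out
}

#' Aggregate guide fold changes to gene-level fitness
#'
#' The gene value is the median of its usable guides' log2 fold changes
#' (robust to individual inactive guides); the standard error is
#' `1.4826 * MAD / sqrt(n_guides)`. Guides flagged low-coverage are excluded;
#' genes left with no usable guide are dropped with a warning.
#'
#' @param guide_lfc Output of [guide_log2fc()].
#' @return Data.frame of class `gene_fitness`: `gene`, `condition`, `lfc`,
#'   `se`, `n_guides`.
#' @export
aggregate_gene_fitness <- function(guide_lfc) {
  usable <- guide_lfc[!guide_lfc$low_coverage & is.finite(guide_lfc$lfc), ]
  dropped <- setdiff(unique(guide_lfc$gene), unique(usable$gene))
  if (length(dropped)) {
    warning(sprintf("%d gene(s) dropped with no usable guide: %s",
                    length(dropped),
                    paste(head(dropped, 5), collapse = ", ")), call. = FALSE)
  }
  sp <- split(usable$lfc, usable$gene)
  out <- data.frame(
    gene = names(sp),
    condition = attr(guide_lfc, "condition") %||% NA_character_,
    lfc = vapply(sp, median, 0),
    se = vapply(sp, function(v) mad(v) / sqrt(length(v)), 0),
    n_guides = vapply(sp, length, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("gene_fitness", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
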