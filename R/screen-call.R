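#' Call synthetic-fitness interactions from paired gene fitness profiles
#'
#' Regresses experimental-condition gene fold changes on control-condition
#' fold changes over all shared genes and asks, per gene, whether removing it
#' significantly improves the fit: the externally studentized residual
#' `t_i = e_i / (s_(i) sqrt(1 - h_ii))` is referenced to a t distribution on
#' `G - 3` degrees of freedom (exactly the leave-one-out F test on the
#' residual-sum-of-squares reduction, since `t_i^2 = F_i`). Two-sided p values
#' are Holm-adjusted across genes.
#'
#' @param control,experimental `gene_fitness` data.frames
#'   ([aggregate_gene_fitness()]); genes are matched by name, and genes
#'   present in only one condition are excluded with a warning.
#' @param alpha_level Family-wise significance level (default 0.05).
#' @return List of class `interaction_calls` with `calls` (data.frame: gene,
#'   x, y, residual, t_stat, p, p_adj, direction, called) and `fit`
#'   (slope, intercept, residual_variance, leverages, df).
#' @export
call_interactions <- function(control, experimental, alpha_level = 0.05) {
  stopifnot(is.data.frame(control), is.data.frame(experimental))
  shared <- intersect(control$gene, experimental$gene)
  only <- setdiff(union(control$gene, experimental$gene), shared)
  if (length(only)) {
    warning(sprintf("%d gene(s) present in only one condition excluded",
                    length(only)), call. = FALSE)
  }
  G <- length(shared)
  if (G < 10) stop("need >= 10 shared genes", call. = FALSE)
  x <- control$lfc[match(shared, control$gene)]
  y <- experimental$lfc[match(shared, experimental$gene)]
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite gene fold changes", call. = FALSE)
  }
  if (var(x) == 0) stop("control fold changes are degenerate (zero variance)",
                        call. = FALSE)
  fit <- lm(y ~ x)
  h <- stats::hatvalues(fit)
  e <- stats::residuals(fit)
  t_stat <- rstudent(fit)  # e_i / (s_(i) sqrt(1 - h_ii))
  # numerical degeneracies: a perfect global fit carries no outlier signal,
  # while a perfect leave-one-out fit around a real outlier is infinite
  # evidence (the deleted variance cancels to ~0 and rstudent returns NaN)
  if (sum(e^2) <= 1e-12 * (G - 1) * var(y)) {
    t_stat[] <- 0
  } else {
    nan <- !is.finite(t_stat)
    t_stat[nan] <- sign(e[nan]) * Inf
  }
  p <- 2 * pt_abs(t_stat, df = G - 3)
  p_adj <- p.adjust(p, method = "holm")
  called <- p_adj < alpha_level
  calls <- data.frame(
    gene = shared, x = x, y = y, residual = e, t_stat = t_stat,
    p = p, p_adj = p_adj,
    direction = ifelse(e >= 0, "enriched", "depleted"),
    called = called, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(calls = calls,
         fit = list(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    residual_variance = sum(e^2) / (G - 2),
                    leverages = unname(h), df = G - 2),
         alpha_level = alpha_level),
    class = "interaction_calls"
  )
}

pt_abs <- function(t, df) stats::pt(abs(t), df = df, lower.tail = FALSE)

#' @export
print.interaction_calls <- function(x, ...) {
  cat(sprintf("<interaction_calls> %d genes, %d called at alpha = %.3g\n",
              nrow(x$calls), sum(x$calls$called), x$alpha_level))
  invisible(x)
}

#' Write interaction calls and the regression summary
#'
#' @param x An `interaction_calls` object.
#' @param path TSV output for the per-gene table; a `<path>.summary.txt`
#'   sidecar records the regression fit.
#' @export
write_interaction_calls <- function(x, path) {
  stopifnot(inherits(x, "interaction_calls"))
  write.table(x$calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- paste0(path, ".summary.txt")
  writeLines(c(
    sprintf("slope\t%.10g", x$fit$slope),
    sprintf("intercept\t%.10g", x$fit$intercept),
    sprintf("residual_variance\t%.10g", x$fit$residual_variance),
    sprintf("df\t%d", x$fit$df),
    sprintf("alpha_level\t%g", x$alpha_level),
    sprintf("n_called\t%d", sum(x$calls$called))
  ), side)
  invisible(path)
}
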