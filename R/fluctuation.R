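#' Luria-Delbruck mutant-count distribution (Ma-Sandri-Sarkar recursion)
#'
#' Exact probability mass function of the number of mutant cells in a culture
#' under the Lea-Coulson model with mutant relative fitness 1: mutation events
#' are Poisson with mean `m` and each event founds a clone whose size follows
#' the classic `1/(k (k + 1))` law. The recursion is
#' \deqn{p_0 = e^{-m}, \qquad p_k = \frac{m}{k} \sum_{j=0}^{k-1}
#'   \frac{p_j}{k - j + 1}.}
#'
#' @param m Expected number of mutation events per culture (>= 0).
#' @param K Truncation index; probabilities are returned for counts `0..K`.
#' @return A list of class `ld_distribution` with fields `m`, `K`, and `p`
#'   (length `K + 1`).
#' @examples
#' d <- luria_delbruck_pmf(1, 10)
#' d$p[1]  # exp(-1)
#' @export
luria_delbruck_pmf <- function(m, K) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m))
  if (m < 0) stop("`m` must be >= 0", call. = FALSE)
  K <- as.integer(K)
  stopifnot(K >= 0)
  p <- numeric(K + 1)
  p[1] <- exp(-m)
  if (K >= 1) {
    for (k in seq_len(K)) {
      j <- 0:(k - 1)
      p[k + 1] <- (m / k) * sum(p[j + 1] / (k - j + 1))
    }
  }
  structure(list(m = m, K = K, p = p), class = "ld_distribution")
}

#' @export
print.ld_distribution <- function(x, ...) {
  cat(sprintf("<ld_distribution> m = %.4g, K = %d, sum(p) = %.4f\n",
              x$m, x$K, sum(x$p)))
  invisible(x)
}

#' Build a fluctuation experiment record
#'
#' @param mutant_counts Non-negative integer mutant counts, one per culture.
#' @param titer Mean final cells per culture (N_t > 0).
#' @param plating_fraction Fraction of each culture plated on selection,
#'   z in (0, 1]. The estimator assumes full plating and warns when z < 1
#'   is declared.
#' @return A list of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(mutant_counts, titer, plating_fraction = 1) {
  stopifnot(is.numeric(mutant_counts), all(is.finite(mutant_counts)),
            all(mutant_counts >= 0), all(mutant_counts == round(mutant_counts)))
  stopifnot(is.numeric(titer), length(titer) == 1L, titer > 0)
  stop_if_not_scalar_prob(plating_fraction, "plating_fraction", open_left = TRUE)
  structure(
    list(mutant_counts = round(mutant_counts), titer = titer,
         plating_fraction = plating_fraction),
    class = "fluctuation_experiment"
  )
}

#' Maximum-likelihood estimate of mutations per culture
#'
#' Fits `m` by maximizing the Ma-Sandri-Sarkar log-likelihood of the observed
#' mutant counts with bounded one-dimensional optimization. The standard
#' error comes from the numerical observed information at the maximum.
#'
#' @param experiment A [fluctuation_experiment()].
#' @return List of class `mss_fit` with `m_hat`, `se_m`, `loglik`,
#'   `n_cultures`, `K`.
#' @export
fit_mss_mle <- function(experiment) {
  stopifnot(inherits(experiment, "fluctuation_experiment"))
  x <- experiment$mutant_counts
  if (length(x) < 2L) stop("need >= 2 cultures", call. = FALSE)
  if (experiment$plating_fraction < 1) {
    warning("plating_fraction < 1 declared; the estimator assumes full plating ",
            "and m_hat refers to plated mutants", call. = FALSE)
  }
  # The recursion is O(K^2); censor astronomical jackpot counts into the tail
  # mass beyond K_cap so the likelihood stays computable and finite.
  K_cap <- 5000L
  K <- min(max(x, 1L), K_cap)
  in_range <- x <= K
  ll <- function(m) {
    p <- luria_delbruck_pmf(m, K)$p
    tail_mass <- max(1 - sum(p), 1e-300)
    sum(log(pmax(p[x[in_range] + 1], 1e-300))) + sum(!in_range) * log(tail_mass)
  }
  if (all(x == 0L)) {
    # Likelihood is exp(-n m): maximized at the boundary m = 0.
    return(structure(list(m_hat = 0, se_m = NA_real_, loglik = 0,
                          n_cultures = length(x), K = K), class = "mss_fit"))
  }
  upper <- 10 * (mean(x) + 1)
  opt <- optimize(ll, interval = c(1e-6, upper), maximum = TRUE, tol = 1e-6)
  if (!is.finite(opt$objective)) {
    stop("MSS likelihood optimization did not converge (objective not finite); ",
         sprintf("m range searched [1e-6, %.3g]", upper), call. = FALSE)
  }
  m_hat <- opt$maximum
  h <- max(1e-4, 1e-4 * m_hat)
  d2 <- (ll(m_hat + h) - 2 * ll(m_hat) + ll(max(m_hat - h, 1e-8))) / h^2
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(list(m_hat = m_hat, se_m = se, loglik = opt$objective,
                 n_cultures = length(x), K = K), class = "mss_fit")
}

#' @export
print.mss_fit <- function(x, ...) {
  cat(sprintf("<mss_fit> m_hat = %.4g (se %.3g), %d cultures\n",
              x$m_hat, x$se_m, x$n_cultures))
  invisible(x)
}

#' Convert mutations per culture to a per-generation mutation rate
#'
#' The conventional estimate divides the expected mutations per culture by the
#' final population size: mu = m / N_t. Because roughly N_t divisions produce
#' a saturated culture, this is the rate per cell per generation. The variant
#' mu = m / (N_t ln 2) is exposed via `per_division = FALSE` for users who
#' prefer the integrated-growth denominator.
#'
#' @param fit An [fit_mss_mle()] result (or a list with `m_hat`, `se_m`).
#' @param titer Final cells per culture, N_t.
#' @param per_division If `FALSE`, divide additionally by `ln 2`.
#' @return List of class `mutation_rate_estimate` with `mu_hat`, `se_mu`,
#'   `ci95`, plus the inputs.
#' @export
mutation_rate_per_generation <- function(fit, titer, per_division = TRUE) {
  stopifnot(is.numeric(titer), length(titer) == 1L, titer > 0)
  denom <- titer * (if (per_division) 1 else log(2))
  mu <- fit$m_hat / denom
  se <- fit$se_m / denom
  ci <- c(max(0, fit$m_hat - 1.96 * fit$se_m), fit$m_hat + 1.96 * fit$se_m) / denom
  structure(list(m_hat = fit$m_hat, se_m = fit$se_m, titer = titer,
                 mu_hat = mu, se_mu = se, ci95 = ci),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("<mutation_rate_estimate> mu_hat = %.4g per generation (95%% CI %.3g-%.3g)\n",
              x$mu_hat, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' One-sided comparison of two mutation-rate estimates
#'
#' Normal-theory z test on the difference of rates, with the alternative that
#' rate `a` is greater (or less) than rate `b`.
#'
#' @param est_a,est_b [mutation_rate_per_generation()] results.
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return List with `z`, `p_value`, `alternative`.
#' @export
compare_mutation_rates <- function(est_a, est_b,
                                   alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  se <- sqrt(est_a$se_mu^2 + est_b$se_mu^2)
  if (!is.finite(se) || se <= 0) {
    stop("pooled standard error is zero or not finite", call. = FALSE)
  }
  z <- (est_a$mu_hat - est_b$mu_hat) / se
  p <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z, lower.tail = TRUE),
    two.sided = 2 * pnorm(abs(z), lower.tail = FALSE)
  )
  list(z = z, p_value = p, alternative = alternative)
}
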