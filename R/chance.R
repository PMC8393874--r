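#' Standard normal quantile with domain checking
#'
#' @param beta Probability strictly in (0, 1) (vectorized).
#' @return The standard normal quantile(s) of `beta`.
#' @export
inverse_normal_cdf <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("inverse_normal_cdf: beta must lie strictly in (0, 1)", call. = FALSE)
  stats::qnorm(beta)
}

#' Deterministic-equivalent readmission threshold
#'
#' Converts the chance constraint "with probability at least `beta`, the mean
#' readmission probability over the condition's patients stays at or below
#' the target `theta`" into its deterministic equivalent. Under the Gaussian
#' response model — each selected plan's realized readmission mean is an
#' independent N(mu_hat, lambda * mu_hat) variable — the constraint holds if
#' and only if the sum `m` of the selected plans' means satisfies
#' `m <= mu_star`, where `mu_star` is the unique positive root of
#'
#'   `theta * n_patients - m = sqrt(lambda * m) * qnorm(beta)`.
#'
#' Substituting `s = sqrt(m)` makes the equation a quadratic in `s` whose two
#' roots have product `-theta * n_patients < 0`, so exactly one root is
#' positive and the closed form
#' `mu_star = ((-sqrt(lambda) z + sqrt(lambda z^2 + 4 theta n)) / 2)^2`
#' with `z = qnorm(beta)` is exact. At `beta = 0.5` (`z = 0`) it collapses to
#' `theta * n_patients`; it is strictly decreasing in `beta`.
#'
#' @param theta Target readmission rate in (0, 1].
#' @param n_patients Number of patients, a positive integer.
#' @param lam Variance scale of the Gaussian response (variance
#'   `lam * mu_hat`), positive.
#' @param beta Confidence level strictly in (0, 1).
#' @return An object of class `chance_threshold` with fields `theta`,
#'   `n_patients`, `lambda`, `beta`, `mu_star` and `degenerate` (TRUE only in
#'   the `theta * n_patients = 0` limit, where the constraint forces zero
#'   readmission mass).
#' @export
#' @examples
#' deterministic_threshold(0.2, 10, 0.25, 0.5)$mu_star   # exactly 2
deterministic_threshold <- function(theta, n_patients, lam, beta) {
  if (!is_prob(theta) || theta < 0 || theta > 1)
    stop("deterministic_threshold: theta must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(n_patients) || n_patients < 0)
    stop("deterministic_threshold: n_patients must be non-negative", call. = FALSE)
  if (!is_prob(lam) || lam <= 0)
    stop("deterministic_threshold: lam must be > 0", call. = FALSE)
  if (!is_prob(beta) || beta <= 0 || beta >= 1)
    stop("deterministic_threshold: beta must lie strictly in (0, 1)", call. = FALSE)
  tp <- theta * n_patients
  if (tp == 0) {
    mu_star <- 0
    degenerate <- TRUE
  } else {
    z <- stats::qnorm(beta)
    s <- (-sqrt(lam) * z + sqrt(lam * z^2 + 4 * tp)) / 2
    mu_star <- if (z == 0) tp else s^2
    degenerate <- FALSE
  }
  structure(list(theta = theta, n_patients = n_patients, lambda = lam,
                 beta = beta, mu_star = mu_star, degenerate = degenerate),
            class = "chance_threshold")
}

#' @export
print.chance_threshold <- function(x, ...) {
  cat(sprintf("<chance_threshold> theta=%.4f |P|=%d lambda=%.3f beta=%.3f -> mu* = %.10g%s\n",
              x$theta, as.integer(x$n_patients), x$lambda, x$beta, x$mu_star,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Threshold by bisection (cross-check for the closed form)
#'
#' Solves `theta * n - m = sqrt(lam * m) * qnorm(beta)` for `m` by bracketed
#' bisection. Slower than the closed form in
#' [deterministic_threshold()]; retained as an in-package numerical
#' cross-check (the two agree to 1e-10 relative).
#'
#' @inheritParams deterministic_threshold
#' @param tol Absolute/relative bisection tolerance.
#' @return The root `mu_star` as a number.
#' @export
threshold_bisection <- function(theta, n_patients, lam, beta, tol = 1e-13) {
  tp <- theta * n_patients
  if (tp == 0) return(0)
  z <- stats::qnorm(beta)
  g <- function(m) tp - m - sqrt(lam * m) * z
  lo <- 0
  hi <- max(tp, 1)
  while (g(hi) > 0) hi <- 2 * hi
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Monte-Carlo coverage of the chance constraint
#'
#' Empirically checks the deterministic-equivalent conversion: given the
#' selected plans' means, draws each patient's realized readmission mean
#' independently from N(mu_hat_p, lam * mu_hat_p) — untruncated, exactly the
#' distribution the conversion assumes — and returns the fraction of draws in
#' which the selected sum stays at or below `theta * n_patients`. A selection
#' placed exactly at the threshold `mu_star(beta)` should achieve coverage
#' `beta` up to Monte-Carlo error.
#'
#' Note the scenario generator truncates its Gaussians into (0, 1) for
#' realism; this oracle deliberately does not, matching the conversion's
#' mathematics.
#'
#' @param mu_hat_selected Numeric vector of the selected plans' means, one
#'   per patient, each in (0, 1).
#' @param theta Target readmission rate.
#' @param lam Variance scale.
#' @param n_draws Number of Monte-Carlo replications.
#' @param seed RNG seed.
#' @return The empirical coverage probability.
#' @export
chance_coverage_oracle <- function(mu_hat_selected, theta, lam,
                                   n_draws = 100000L, seed = 1L) {
  mu <- as.numeric(mu_hat_selected)
  if (!length(mu)) stop("chance_coverage_oracle: empty selection", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("chance_coverage_oracle: selected means must lie in (0, 1)", call. = FALSE)
  if (!is_count(n_draws)) stop("chance_coverage_oracle: n_draws must be >= 1", call. = FALSE)
  cap <- theta * length(mu)
  sds <- sqrt(lam * mu)
  with_seed(seed, {
    hits <- 0L
    done <- 0L
    chunk <- max(1L, min(as.integer(n_draws), as.integer(2e7 / length(mu))))
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      draws <- matrix(stats::rnorm(m * length(mu), mean = mu, sd = sds),
                      nrow = length(mu))
      hits <- hits + sum(colSums(draws) <= cap)
      done <- done + m
    }
    hits / n_draws
  })
}
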