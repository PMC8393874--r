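# Independent numerical oracles used to freeze expected values. These
# deliberately avoid the code paths (and distribution functions) they check:
# the normal CDF comes from quadrature of the density, its inverse from
# bisection, thresholds from bisection on the defining equation, and optimal
# assignments from exhaustive enumeration.

# Standard normal CDF via quadrature of exp(-t^2/2)/sqrt(2*pi).
phi_quad <- function(x) {
  0.5 + stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi), 0, x,
                         rel.tol = 1e-13, abs.tol = 1e-14)$value
}

# Inverse normal CDF by bisection on phi_quad.
phi_inv_quad <- function(p, tol = 1e-12) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (phi_quad(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Deterministic-equivalent threshold by bisection on
# theta*n - m = sqrt(lam*m) * z, using the quadrature-based quantile.
mu_star_oracle <- function(theta, n_patients, lam, beta, tol = 1e-12) {
  tp <- theta * n_patients
  z <- phi_inv_quad(beta)
  g <- function(m) tp - m - sqrt(lam * m) * z
  lo <- 0; hi <- max(tp, 1)
  while (g(hi) > 0) hi <- 2 * hi
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random small assignment instance for solver-vs-enumeration checks.
rand_instance <- function(seed) {
  set.seed(seed)
  P <- sample(1:4, 1)
  K <- sample(2:3, 1)
  costs <- matrix(round(runif(P * K, 10, 100), 2), P, K)
  mu <- matrix(runif(P * K, 0.01, 0.5), P, K)
  # mix slack, binding and infeasible caps
  cap <- runif(1, 0.2, 1.4) * sum(apply(mu, 1, stats::median))
  list(costs = costs, mu = mu, cap = cap)
}

# Small two-condition hospital for fast end-to-end tests.
make_tiny_spec <- function(penalty = 10000) {
  hospital_spec("tiny", list(
    condition_spec("C1", target_rate = 0.26, hospital_mean_rate = 0.22,
                   n_patients = 4, cost_triangular = c(100, 200, 400),
                   n_plans = 4, tier_sizes = c(1, 2, 1)),
    condition_spec("C2", target_rate = 0.10, hospital_mean_rate = 0.06,
                   n_patients = 5, cost_triangular = c(50, 80, 200),
                   n_plans = 4, tier_sizes = c(1, 2, 1))
  ), annual_penalty = penalty)
}

# Hand-built scenario set wrapping explicit cost / mu matrices (lists of
# P x K matrices, one per scenario, per condition id).
fake_scenario_set <- function(spec, cost_by_cond, mu_by_cond,
                              p = NULL) {
  ids <- names(cost_by_cond)
  n_scen <- length(cost_by_cond[[1]])
  if (is.null(p)) p <- rep(1 / n_scen, n_scen)
  conds <- lapply(ids, function(id) {
    cs <- spec$conditions[[id]]
    P <- nrow(cost_by_cond[[id]][[1]]); K <- ncol(cost_by_cond[[id]][[1]])
    list(id = id,
         cost = array(unlist(cost_by_cond[[id]]), c(P, K, n_scen)),
         mu_hat = array(unlist(mu_by_cond[[id]]), c(P, K, n_scen)),
         tiers = rep(seq_along(cs$tier_sizes), cs$tier_sizes))
  })
  names(conds) <- ids
  structure(list(p = p, n_scenarios = n_scen, conditions = conds,
                 provenance = list(hospital_id = spec$hospital_id,
                                   settings = generator_settings())),
            class = "scenario_set")
}
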