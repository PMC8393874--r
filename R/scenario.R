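#' Settings for the scenario generator
#'
#' Controls the link between a patient's baseline readmission mean and the
#' per-plan means, the truncation of generated probabilities, and cost
#' ordering. Tier multipliers scale the patient baseline: Tier 1 plans
#' (intensive, expensive) multiply it by a draw from `(0.4, 0.7)` by default,
#' the middle tier by `(0.7, 1.0)` and the last tier by `(1.0, 1.3)`, so the
#' expected tier ordering — higher cost, lower readmission — holds by
#' construction. Midpoints must increase strictly across tiers.
#'
#' @param seed Integer seed driving every draw; one named stream is derived
#'   per (condition position, scenario), so appending conditions or scenarios
#'   leaves existing draws unchanged.
#' @param tier_multiplier_ranges List of `c(low, high)` pairs, one per tier.
#' @param prob_bounds Truncation interval for generated probabilities,
#'   default `c(0.001, 0.999)`; baselines are resampled into it and per-plan
#'   means clipped to it.
#' @param cost_sorting When `TRUE` (default), per-patient plan costs are
#'   sorted in decreasing order over the plan index so that Tier 1 (low plan
#'   indices) is the expensive end.
#' @return An object of class `generator_settings`.
#' @export
generator_settings <- function(seed = 1L,
                               tier_multiplier_ranges = list(c(0.4, 0.7),
                                                             c(0.7, 1.0),
                                                             c(1.0, 1.3)),
                               prob_bounds = c(0.001, 0.999),
                               cost_sorting = TRUE) {
  rng <- lapply(tier_multiplier_ranges, as.numeric)
  if (any(vapply(rng, function(r) length(r) != 2L || r[1] > r[2] || r[1] <= 0,
                 logical(1))))
    stop("generator_settings: each tier range must be positive with low <= high",
         call. = FALSE)
  mid <- vapply(rng, mean, numeric(1))
  if (length(mid) > 1L && any(diff(mid) <= 0))
    stop("generator_settings: tier multiplier midpoints must increase strictly",
         call. = FALSE)
  if (length(prob_bounds) != 2L || prob_bounds[1] <= 0 || prob_bounds[2] >= 1 ||
      prob_bounds[1] >= prob_bounds[2])
    stop("generator_settings: prob_bounds must satisfy 0 < lo < hi < 1",
         call. = FALSE)
  structure(list(seed = as.integer(seed), tier_multiplier_ranges = rng,
                 prob_bounds = as.numeric(prob_bounds),
                 cost_sorting = isTRUE(cost_sorting)),
            class = "generator_settings")
}

#' Scenario count needed to estimate a mean to a given precision
#'
#' Smallest integer strictly greater than `(z[alpha/2])^2 * s2 / eps^2`, with
#' floor 1 — the classic sample-size bound for estimating a population mean
#' with `confidence` and error at most `eps`, seeded with a pilot variance
#' estimate `s2`.
#'
#' @param sample_variance Pilot variance estimate `s2 >= 0` (e.g. the
#'   objective's variance over a small pilot scenario set).
#' @param confidence Confidence level `1 - alpha`, strictly in (0, 1).
#' @param tolerance Half-width `eps > 0`, in the units of the estimated mean.
#' @return A positive integer scenario count.
#' @export
#' @examples
#' required_scenario_count(156721.15, 0.99, 150)  # 47
required_scenario_count <- function(sample_variance, confidence, tolerance) {
  if (!is_prob(sample_variance) || sample_variance < 0)
    stop("required_scenario_count: sample_variance must be >= 0", call. = FALSE)
  if (!is_prob(confidence) || confidence <= 0 || confidence >= 1)
    stop("required_scenario_count: confidence must lie in (0, 1)", call. = FALSE)
  if (!is_prob(tolerance) || tolerance <= 0)
    stop("required_scenario_count: tolerance must be > 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  bound <- z^2 * sample_variance / tolerance^2
  max(1L, as.integer(floor(bound)) + 1L)
}

#' Triangular distribution quantile
#'
#' Inverse CDF of the triangular distribution with support `tri = c(min,
#' mode, max)`. Used internally for cost draws; exported because cost models
#' built on low/fair/high price triples lean on it directly.
#'
#' @param u Probabilities in `[0, 1]` (vectorized).
#' @param tri Numeric triple `c(min, mode, max)` with `min <= mode <= max`.
#' @return Quantiles on the cost scale.
#' @export
triangular_quantile <- function(u, tri) {
  tri <- as.numeric(tri)
  if (length(tri) != 3L || anyNA(tri) || tri[1] > tri[2] || tri[2] > tri[3])
    stop("triangular_quantile: tri must be c(min, mode, max) with min <= mode <= max",
         call. = FALSE)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("triangular_quantile: u must lie in [0, 1]", call. = FALSE)
  a <- tri[1]; m <- tri[2]; b <- tri[3]
  if (a == b) return(rep(a, length(u)))
  fc <- (m - a) / (b - a)
  ifelse(u <= fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

# Triangular mean (min + mode + max) / 3; shared with the economics module.
triangular_mean <- function(tri) sum(as.numeric(tri)) / 3

# Gaussian draws truncated to (lo, hi) by resampling.
rnorm_truncated <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate cost and readmission-mean scenarios for a hospital instance
#'
#' Each scenario realizes, for every condition, a `|P| x |K|` matrix of
#' treatment-plan costs and a matching matrix of per-plan readmission-
#' probability means:
#' \itemize{
#'   \item each patient gets a baseline readmission mean drawn from a
#'     Gaussian centred at the hospital's mean rate mu_c with standard
#'     deviation `lambda_c * mu_c` (lambda as a coefficient of variation),
#'     resampled into the settings' probability bounds — so the grand mean of
#'     baselines stays anchored at mu_c;
#'   \item each plan's mean is the baseline times a multiplier drawn uniformly
#'     from its tier's range, clipped to the bounds — Tier 1 reduces
#'     readmission most;
#'   \item each plan's cost is an independent draw from the condition's
#'     triangular distribution; by default the draws are sorted in decreasing
#'     order over the plan index, so low plan indices (Tier 1) are the
#'     expensive, effective end.
#' }
#' Scenario probabilities are equal, `p = 1/n_scenarios`. Output is fully
#' reproducible from the settings seed.
#'
#' @param spec A [hospital_spec()].
#' @param n_scenarios Number of scenarios, `>= 1`.
#' @param settings A [generator_settings()].
#' @return An object of class `scenario_set`: list with elements `p`
#'   (scenario probabilities), `conditions` (per condition: `cost` and
#'   `mu_hat` arrays of dim `|P| x |K| x n_scenarios`, plus `tiers`, the tier
#'   index of each plan), and `provenance`.
#' @export
generate_scenarios <- function(spec, n_scenarios,
                               settings = generator_settings()) {
  stopifnot(inherits(spec, "hospital_spec"),
            inherits(settings, "generator_settings"))
  if (!is_count(n_scenarios))
    stop("generate_scenarios: n_scenarios must be a positive integer", call. = FALSE)
  n_scenarios <- as.integer(n_scenarios)
  lo <- settings$prob_bounds[1]; hi <- settings$prob_bounds[2]
  n_tiers <- length(settings$tier_multiplier_ranges)

  conds <- lapply(seq_along(spec$conditions), function(ci) {
    cs <- spec$conditions[[ci]]
    if (length(cs$tier_sizes) != n_tiers)
      stop(sprintf("generate_scenarios: condition '%s' has %d tiers but settings provide %d multiplier ranges",
                   cs$id, length(cs$tier_sizes), n_tiers), call. = FALSE)
    P <- cs$n_patients; K <- cs$n_plans
    tiers <- rep(seq_along(cs$tier_sizes), cs$tier_sizes)
    lo_t <- vapply(settings$tier_multiplier_ranges, `[`, numeric(1), 1)[tiers]
    hi_t <- vapply(settings$tier_multiplier_ranges, `[`, numeric(1), 2)[tiers]
    cost <- array(NA_real_, c(P, K, n_scenarios))
    mu_hat <- array(NA_real_, c(P, K, n_scenarios))
    # lambda acts as a coefficient of variation here: the scenario baselines
    # scatter around the hospital mean with sd = lambda * mean, keeping the
    # truncation essentially inactive and the sample mean anchored at mu_c.
    # (The chance-constraint conversion, a different layer, uses variance
    # lambda * mu_hat as its Gaussian response model requires.)
    sd_c <- cs$lambda * cs$hospital_mean_rate
    for (w in seq_len(n_scenarios)) {
      with_seed(derive_stream_seed(settings$seed, ci, w), {
        baseline <- rnorm_truncated(P, cs$hospital_mean_rate, sd_c, lo, hi)
        mult <- matrix(stats::runif(P * K, rep(lo_t, each = P), rep(hi_t, each = P)),
                       P, K)
        mu_hat[, , w] <- clip(baseline * mult, lo, hi)
        cw <- matrix(triangular_quantile(stats::runif(P * K), cs$cost_triangular),
                     P, K)
        if (settings$cost_sorting)
          cw <- matrix(t(apply(cw, 1, sort, decreasing = TRUE)), P, K)
        cost[, , w] <- cw
      })
    }
    list(id = cs$id, cost = cost, mu_hat = mu_hat, tiers = tiers)
  })
  names(conds) <- condition_ids(spec)
  structure(list(
    p = rep(1 / n_scenarios, n_scenarios),
    n_scenarios = n_scenarios,
    conditions = conds,
    provenance = list(hospital_id = spec$hospital_id, settings = settings)
  ), class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> %d scenarios, %d conditions (hospital %s, seed %d)\n",
              x$n_scenarios, length(x$conditions),
              x$provenance$hospital_id, x$provenance$settings$seed))
  invisible(x)
}

#' Export / import a scenario set
#'
#' The long CSV has one row per (scenario, condition, patient, plan) with
#' columns `scenario, condition, patient, plan, tier, cost, mu_hat`; the JSON
#' sidecar carries scenario probabilities, the seed and generator settings.
#' Numbers are written at full double precision so a round trip reproduces
#' the set exactly.
#'
#' @param scenarios A `scenario_set`.
#' @param csv_path Path for the long CSV.
#' @param json_path Path for the JSON sidecar; defaults to
#'   `paste0(csv_path, ".json")`.
#' @return `write_scenario_set` returns the paths invisibly;
#'   `read_scenario_set` returns a `scenario_set`.
#' @export
write_scenario_set <- function(scenarios, csv_path,
                               json_path = paste0(csv_path, ".json")) {
  stopifnot(inherits(scenarios, "scenario_set"))
  rows <- do.call(rbind, lapply(names(scenarios$conditions), function(id) {
    cc <- scenarios$conditions[[id]]
    d <- dim(cc$cost)  # P x K x W
    grid <- expand.grid(patient = seq_len(d[1]), plan = seq_len(d[2]),
                        scenario = seq_len(d[3]))
    data.frame(scenario = grid$scenario, condition = id,
               patient = grid$patient, plan = grid$plan,
               tier = cc$tiers[grid$plan],
               cost = sprintf("%.17g", cc$cost[as.matrix(grid)]),
               mu_hat = sprintf("%.17g", cc$mu_hat[as.matrix(grid)]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    p = sprintf("%.17g", scenarios$p),
    n_scenarios = scenarios$n_scenarios,
    hospital_id = scenarios$provenance$hospital_id,
    settings = list(
      seed = scenarios$provenance$settings$seed,
      tier_multiplier_ranges = scenarios$provenance$settings$tier_multiplier_ranges,
      prob_bounds = scenarios$provenance$settings$prob_bounds,
      cost_sorting = scenarios$provenance$settings$cost_sorting
    )
  )
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_scenario_set
#' @export
read_scenario_set <- function(csv_path, json_path = paste0(csv_path, ".json")) {
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  rows <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                          colClasses = c(cost = "numeric", mu_hat = "numeric"))
  conds <- lapply(split(rows, factor(rows$condition, levels = unique(rows$condition))),
                  function(d) {
    P <- max(d$patient); K <- max(d$plan); W <- max(d$scenario)
    idx <- cbind(d$patient, d$plan, d$scenario)
    cost <- array(NA_real_, c(P, K, W)); cost[idx] <- d$cost
    mu <- array(NA_real_, c(P, K, W)); mu[idx] <- d$mu_hat
    tiers <- integer(K)
    tiers[d$plan] <- d$tier
    list(id = d$condition[1], cost = cost, mu_hat = mu, tiers = tiers)
  })
  conds <- conds[unique(rows$condition)]
  settings <- generator_settings(
    seed = side$settings$seed,
    tier_multiplier_ranges = lapply(seq_len(nrow(side$settings$tier_multiplier_ranges)),
                                    function(i) side$settings$tier_multiplier_ranges[i, ]),
    prob_bounds = side$settings$prob_bounds,
    cost_sorting = side$settings$cost_sorting
  )
  structure(list(
    p = as.numeric(side$p),
    n_scenarios = as.integer(side$n_scenarios),
    conditions = conds,
    provenance = list(hospital_id = side$hospital_id, settings = settings)
  ), class = "scenario_set")
}
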