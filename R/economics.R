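#' Mean treatment-plan cost for a condition
#'
#' Analytic mean of the condition's triangular cost distribution,
#' `(min + mode + max) / 3`.
#'
#' @param condition A [condition_spec()].
#' @return Mean cost in USD.
#' @export
mean_plan_cost <- function(condition) {
  stopifnot(inherits(condition, "condition_spec"))
  triangular_mean(condition$cost_triangular)
}

#' Penalty cost-share model
#'
#' Each condition contributes a share of the annual penalty proportional to
#' its expected treatment spend: `R_c = |P_c| abar_c / sum(|P| abar)`, where
#' `abar_c` is the condition's mean plan cost. By default `abar_c` is the
#' analytic triangular mean from the spec; set `empirical = TRUE` (with a
#' scenario set) to use the empirical scenario cost mean instead.
#'
#' @param spec A [hospital_spec()].
#' @param empirical Use empirical scenario cost means for `abar_c`.
#' @param scenarios Scenario set, required when `empirical = TRUE`.
#' @return An object of class `penalty_model`: data frame `shares` (condition,
#'   n_patients, mean_cost, share) plus the annual penalty.
#' @export
cost_shares <- function(spec, empirical = FALSE, scenarios = NULL) {
  stopifnot(inherits(spec, "hospital_spec"))
  ids <- condition_ids(spec)
  abar <- if (empirical) {
    if (is.null(scenarios)) stop("cost_shares: empirical = TRUE needs scenarios",
                                 call. = FALSE)
    vapply(ids, function(id) mean(scenarios$conditions[[id]]$cost), numeric(1))
  } else {
    vapply(spec$conditions, mean_plan_cost, numeric(1))
  }
  n_p <- vapply(spec$conditions, `[[`, integer(1), "n_patients")
  w <- n_p * abar
  if (sum(w) <= 0) stop("cost_shares: total expected spend is zero", call. = FALSE)
  structure(list(
    shares = data.frame(condition = ids, n_patients = n_p, mean_cost = abar,
                        share = w / sum(w), row.names = NULL),
    annual_penalty = spec$annual_penalty
  ), class = "penalty_model")
}

#' Expected penalty for a confidence-level vector
#'
#' `EP(beta) = sum_c (1 - beta_c) * R_c * Penalty`: each condition's slice of
#' the annual penalty, weighted by the probability `1 - beta_c` that its care
#' strategy misses the target.
#'
#' @param beta Per-condition confidence levels (named by condition id, or
#'   positional in the model's condition order; a single value is recycled).
#' @param model A [cost_shares()] penalty model.
#' @return Expected penalty in USD.
#' @export
expected_penalty <- function(beta, model) {
  stopifnot(inherits(model, "penalty_model"))
  ids <- model$shares$condition
  if (length(beta) == 1L) beta <- rep(beta, length(ids))
  if (!is.null(names(beta))) beta <- beta[ids]
  if (length(beta) != length(ids) || anyNA(beta))
    stop("expected_penalty: need one beta per condition", call. = FALSE)
  sum((1 - as.numeric(beta)) * model$shares$share) * model$annual_penalty
}

#' Baseline cost levels
#'
#' `no_penalty` is the hospital's expected treatment spend if the penalty
#' policy did not exist: `sum_c |P_c| * abar_c`. `with_penalty` adds the
#' annual penalty on top — the hospital's current situation. Any strategy
#' whose objective beats `with_penalty` saves money.
#'
#' @param spec A [hospital_spec()].
#' @return List with `no_penalty` and `with_penalty` (USD).
#' @export
baseline_costs <- function(spec) {
  stopifnot(inherits(spec, "hospital_spec"))
  no_pen <- sum(vapply(spec$conditions,
                       function(cs) cs$n_patients * mean_plan_cost(cs),
                       numeric(1)))
  list(no_penalty = no_pen, with_penalty = no_pen + spec$annual_penalty)
}

#' Scenario-averaged mean readmission per condition
#'
#' For each condition, the scenario-probability-weighted average of the sum
#' of the chosen plans' readmission means, reported per patient (divided by
#' `|P_c|`) so it is directly comparable with the target rate; the raw sum is
#' kept as an auxiliary column.
#'
#' @param solution A solved [solve_dem()] result.
#' @param spec The matching [hospital_spec()].
#' @return Data frame with columns `condition`, `mean_readmission` (per
#'   patient), `mean_readmission_sum` (raw expected sum), `target_rate`,
#'   `hospital_mean_rate`.
#' @export
mean_readmission_summary <- function(solution, spec) {
  stopifnot(inherits(solution, "care_strategy_solution"),
            inherits(spec, "hospital_spec"))
  if (!identical(solution$status, "solved"))
    stop("mean_readmission_summary: solution is not solved", call. = FALSE)
  ids <- condition_ids(spec)
  rows <- lapply(ids, function(id) {
    d <- solution$results[solution$results$condition == id, ]
    raw <- sum(solution$p[d$scenario] * d$mu_sum)
    cs <- spec$conditions[[id]]
    data.frame(condition = id, mean_readmission = raw / cs$n_patients,
               mean_readmission_sum = raw, target_rate = cs$target_rate,
               hospital_mean_rate = cs$hospital_mean_rate)
  })
  do.call(rbind, rows)
}

#' Expected tier mix of the chosen care strategy
#'
#' Scenario-probability-weighted percentage of patients assigned to each
#' tier, per condition. Rows sum to 100.
#'
#' @inheritParams mean_readmission_summary
#' @return Data frame with `condition` and one `tierT` percentage column per
#'   tier.
#' @export
tier_shares <- function(solution, spec) {
  stopifnot(inherits(solution, "care_strategy_solution"),
            inherits(spec, "hospital_spec"))
  if (!identical(solution$status, "solved"))
    stop("tier_shares: solution is not solved", call. = FALSE)
  ids <- condition_ids(spec)
  n_tiers <- max(vapply(spec$conditions, function(cs) length(cs$tier_sizes),
                        integer(1)))
  rows <- lapply(ids, function(id) {
    cs <- spec$conditions[[id]]
    tiers <- rep(seq_along(cs$tier_sizes), cs$tier_sizes)
    amat <- solution$assignments[[id]]          # P x n_scenarios
    share <- numeric(n_tiers)
    for (w in seq_len(ncol(amat))) {
      cnt <- tabulate(tiers[amat[, w]], nbins = n_tiers)
      share <- share + solution$p[w] * cnt / cs$n_patients
    }
    out <- data.frame(condition = id)
    for (t in seq_len(n_tiers)) out[[paste0("tier", t)]] <- 100 * share[t]
    out
  })
  do.call(rbind, rows)
}

#' Sweep confidence levels and tabulate the trade-offs
#'
#' Runs [solve_dem()] across a grid of confidence levels, either moving all
#' conditions together (`mode = "all_conditions"`) or varying one condition
#' while the others stay fixed (`mode = "<condition id>"`; the fixed level
#' defaults to each condition's own highest feasible `beta_star`). Each row
#' carries the expected treatment cost, expected penalty, objective, both
#' baselines, and per-condition mean readmission and tier shares; infeasible
#' grid points carry only the flag.
#'
#' @param spec A [hospital_spec()].
#' @param scenarios A matching scenario set.
#' @param beta_grid Grid of confidence levels in (0, 1).
#' @param mode `"all_conditions"` or a condition id.
#' @param fixed_beta Level at which non-swept conditions are held in
#'   single-condition mode; default their per-condition `beta_star`.
#' @return A `sweep_result` data frame.
#' @export
beta_sweep <- function(spec, scenarios, beta_grid = default_beta_grid(),
                       mode = "all_conditions", fixed_beta = NULL) {
  stopifnot(inherits(spec, "hospital_spec"), inherits(scenarios, "scenario_set"))
  ids <- condition_ids(spec)
  if (!identical(mode, "all_conditions") && !mode %in% ids)
    stop(sprintf("beta_sweep: mode must be 'all_conditions' or one of: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  beta_grid <- sort(as.numeric(beta_grid))
  base <- baseline_costs(spec)
  if (!identical(mode, "all_conditions") && is.null(fixed_beta)) {
    bstar <- max_feasible_beta(scenarios, spec, beta_grid)$per_condition
    if (anyNA(bstar))
      stop("beta_sweep: no feasible fixed level for some condition; supply fixed_beta",
           call. = FALSE)
    fixed_beta <- bstar
  }
  rows <- lapply(beta_grid, function(b) {
    beta <- if (identical(mode, "all_conditions")) {
      beta_vector(spec, b)
    } else {
      bv <- beta_vector(spec, fixed_beta)
      bv[[mode]] <- b
      bv
    }
    sol <- solve_dem(scenarios, beta, spec)
    row <- data.frame(mode = if (identical(mode, "all_conditions")) mode
                             else paste0("single_condition:", mode),
                      beta = b, feasible = identical(sol$status, "solved"),
                      expected_cost = NA_real_, expected_penalty = NA_real_,
                      objective = NA_real_,
                      baseline_no_penalty = base$no_penalty,
                      baseline_with_penalty = base$with_penalty)
    for (id in ids) {
      row[[paste0("mean_readmission_", id)]] <- NA_real_
      row[[paste0(id, "_tier1")]] <- NA_real_
      row[[paste0(id, "_tier2")]] <- NA_real_
      row[[paste0(id, "_tier3")]] <- NA_real_
    }
    if (row$feasible) {
      row$expected_cost <- sol$expected_treatment_cost
      row$expected_penalty <- sol$expected_penalty
      row$objective <- sol$objective
      mrs <- mean_readmission_summary(sol, spec)
      ts <- tier_shares(sol, spec)
      for (id in ids) {
        row[[paste0("mean_readmission_", id)]] <-
          mrs$mean_readmission[mrs$condition == id]
        tr <- ts[ts$condition == id, ]
        for (t in 1:3)
          if (!is.null(tr[[paste0("tier", t)]]))
            row[[paste0(id, "_tier", t)]] <- tr[[paste0("tier", t)]]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}
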