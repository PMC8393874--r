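#' Solve one condition-scenario assignment problem exactly
#'
#' Picks one treatment plan per patient minimizing total cost subject to the
#' deterministic-equivalent readmission cap: the sum of the chosen plans'
#' readmission means must not exceed `mu_star`. This is a multiple-choice
#' knapsack; it is solved exactly by branch-and-bound with an LP-relaxation
#' bound (no rounding heuristics). Among equal-cost optima the
#' lexicographically smallest plan-index vector is returned. The constraint
#' is enforced to 1e-9 absolute.
#'
#' @param costs `|P| x |K|` matrix of plan costs (USD).
#' @param mu_hat `|P| x |K|` matrix of plan readmission means.
#' @param mu_star Non-negative cap on the sum of selected means (see
#'   [deterministic_threshold()]).
#' @param condition_id,scenario Optional labels carried into the result.
#' @return An object of class `assignment_result`: fields `condition_id`,
#'   `scenario`, `status` (`"solved"` or `"infeasible"`), `feasible`,
#'   `assignment` (chosen plan index per patient), `total_cost`, `total_mu`,
#'   `mu_star`, and for infeasible instances `margin`, the amount by which
#'   even the minimal-mean selection overshoots the cap.
#' @export
#' @examples
#' costs <- rbind(c(10, 4), c(10, 4))
#' mus   <- rbind(c(0.1, 0.25), c(0.1, 0.25))
#' solve_condition_scenario(costs, mus, mu_star = 0.40)
solve_condition_scenario <- function(costs, mu_hat, mu_star,
                                     condition_id = NA_character_,
                                     scenario = NA_integer_) {
  costs <- as.matrix(costs); mu_hat <- as.matrix(mu_hat)
  if (!all(dim(costs) == dim(mu_hat)))
    stop("solve_condition_scenario: costs and mu_hat must have the same shape",
         call. = FALSE)
  if (!is.numeric(mu_star) || length(mu_star) != 1L || !is.finite(mu_star) ||
      mu_star < 0)
    stop("solve_condition_scenario: mu_star must be a non-negative number",
         call. = FALSE)
  raw <- solve_mckp_cpp(costs, mu_hat, mu_star)
  assignment_result(raw, costs, mu_hat, mu_star, condition_id, scenario)
}

assignment_result <- function(raw, costs, mu_hat, mu_star, condition_id,
                              scenario) {
  P <- nrow(costs)
  if (isTRUE(raw$feasible)) {
    a <- as.integer(raw$assignment)
    pick <- cbind(seq_len(P), a)
    structure(list(condition_id = condition_id, scenario = scenario,
                   status = "solved", feasible = TRUE, assignment = a,
                   total_cost = sum(costs[pick]), total_mu = sum(mu_hat[pick]),
                   mu_star = mu_star, margin = 0),
              class = "assignment_result")
  } else {
    structure(list(condition_id = condition_id, scenario = scenario,
                   status = "infeasible", feasible = FALSE,
                   assignment = rep(NA_integer_, P),
                   total_cost = NA_real_, total_mu = NA_real_,
                   mu_star = mu_star, margin = raw$margin),
              class = "assignment_result")
  }
}

#' @export
print.assignment_result <- function(x, ...) {
  if (x$feasible)
    cat(sprintf("<assignment_result> %s/scenario %s: cost %.2f, mu %.6g <= mu* %.6g\n",
                x$condition_id, format(x$scenario), x$total_cost, x$total_mu,
                x$mu_star))
  else
    cat(sprintf("<assignment_result> %s/scenario %s: INFEASIBLE (margin %.6g over mu* %.6g)\n",
                x$condition_id, format(x$scenario), x$margin, x$mu_star))
  invisible(x)
}

#' Exhaustive-enumeration oracle for the assignment problem
#'
#' Enumerates every one-plan-per-patient assignment (requires
#' `|K|^|P| <= max_size`) and returns the cost-minimal feasible one under the
#' same tie-breaking contract as [solve_condition_scenario()]
#' (lexicographically smallest plan indices among equal-cost optima). Used as
#' an independent correctness oracle for the branch-and-bound solver.
#'
#' @inheritParams solve_condition_scenario
#' @param max_size Refuse instances with more than this many assignments.
#' @return An `assignment_result`.
#' @export
brute_force_oracle <- function(costs, mu_hat, mu_star,
                               condition_id = NA_character_,
                               scenario = NA_integer_, max_size = 1e6) {
  costs <- as.matrix(costs); mu_hat <- as.matrix(mu_hat)
  P <- nrow(costs); K <- ncol(costs)
  if (K^P > max_size)
    stop("brute_force_oracle: instance too large to enumerate", call. = FALSE)
  combos <- as.matrix(expand.grid(rep(list(seq_len(K)), P)))
  colnames(combos) <- NULL
  # lexicographic order with patient 1 most significant
  combos <- combos[do.call(order, as.data.frame(combos)), , drop = FALSE]
  tot_cost <- numeric(nrow(combos)); tot_mu <- numeric(nrow(combos))
  for (p in seq_len(P)) {
    tot_cost <- tot_cost + costs[p, combos[, p]]
    tot_mu <- tot_mu + mu_hat[p, combos[, p]]
  }
  feas <- tot_mu <= mu_star + 1e-9
  if (!any(feas)) {
    margin <- sum(apply(mu_hat, 1, min)) - mu_star
    return(assignment_result(list(feasible = FALSE, margin = margin),
                             costs, mu_hat, mu_star, condition_id, scenario))
  }
  best <- min(tot_cost[feas])
  tol <- 1e-9 * max(1, abs(best))
  winner <- which(feas & tot_cost <= best + tol)[1]  # first in lex order
  assignment_result(list(feasible = TRUE, assignment = combos[winner, ]),
                    costs, mu_hat, mu_star, condition_id, scenario)
}

#' Solve the full deterministic-equivalent model
#'
#' Computes the deterministic-equivalent cap `mu_star_c(beta_c)` per
#' condition (scenario-invariant, since target, patient count and variance
#' scale do not vary by scenario), solves every (condition, scenario)
#' assignment independently — the model decomposes because the objective is
#' separable and no constraint couples conditions or scenarios — and
#' assembles the objective: expected treatment cost plus the expected
#' penalty.
#'
#' @param scenarios A [generate_scenarios()] scenario set.
#' @param beta A confidence level (recycled) or per-condition vector; see
#'   [beta_vector()].
#' @param spec The [hospital_spec()] the scenarios were generated from.
#' @return An object of class `care_strategy_solution`. When every
#'   (condition, scenario) is feasible: `status "solved"`, per-pair results in
#'   `$results` (data frame) and `$assignments` (per condition, a
#'   `|P| x n_scenarios` matrix of chosen plans), `expected_treatment_cost`,
#'   `expected_penalty`, `objective`. Otherwise `status "infeasible"` with
#'   the failing pairs in `$infeasible_pairs`.
#' @export
solve_dem <- function(scenarios, beta, spec) {
  stopifnot(inherits(scenarios, "scenario_set"), inherits(spec, "hospital_spec"))
  beta <- beta_vector(spec, beta)
  ids <- condition_ids(spec)
  if (!setequal(names(scenarios$conditions), ids))
    stop("solve_dem: scenario set and spec disagree on conditions", call. = FALSE)
  thresholds <- lapply(ids, function(id) {
    cs <- spec$conditions[[id]]
    deterministic_threshold(cs$target_rate, cs$n_patients, cs$lambda, beta[[id]])
  })
  names(thresholds) <- ids

  res_rows <- list(); assigns <- list(); infeas <- list()
  for (id in ids) {
    cc <- scenarios$conditions[[id]]
    P <- dim(cc$cost)[1]; K <- dim(cc$cost)[2]
    amat <- matrix(NA_integer_, P, scenarios$n_scenarios)
    for (w in seq_len(scenarios$n_scenarios)) {
      r <- solve_condition_scenario(matrix(cc$cost[, , w], P, K),
                                    matrix(cc$mu_hat[, , w], P, K),
                                    thresholds[[id]]$mu_star, id, w)
      if (!r$feasible) {
        infeas[[length(infeas) + 1L]] <-
          data.frame(condition = id, scenario = w, margin = r$margin)
      } else {
        amat[, w] <- r$assignment
        res_rows[[length(res_rows) + 1L]] <-
          data.frame(condition = id, scenario = w, cost = r$total_cost,
                     mu_sum = r$total_mu, mu_star = r$mu_star)
      }
    }
    assigns[[id]] <- amat
  }
  if (length(infeas)) {
    return(structure(list(status = "infeasible", beta = beta,
                          infeasible_pairs = do.call(rbind, infeas),
                          thresholds = thresholds),
                     class = "care_strategy_solution"))
  }
  results <- do.call(rbind, res_rows)
  p_w <- scenarios$p
  per_scen_cost <- tapply(results$cost, results$scenario, sum)
  expected_cost <- sum(p_w[as.integer(names(per_scen_cost))] * per_scen_cost)
  model <- cost_shares(spec)
  ep <- expected_penalty(beta, model)
  structure(list(status = "solved", beta = beta, thresholds = thresholds,
                 results = results, assignments = assigns,
                 expected_treatment_cost = expected_cost,
                 expected_penalty = ep,
                 objective = expected_cost + ep,
                 p = p_w),
            class = "care_strategy_solution")
}

#' @export
print.care_strategy_solution <- function(x, ...) {
  if (identical(x$status, "solved")) {
    cat(sprintf("<care_strategy_solution> objective $%.2f = expected cost $%.2f + expected penalty $%.2f\n",
                x$objective, x$expected_treatment_cost, x$expected_penalty))
    cat("  beta:", paste(sprintf("%s=%.2f", names(x$beta), x$beta), collapse = ", "), "\n")
  } else {
    cat(sprintf("<care_strategy_solution> INFEASIBLE for %d (condition, scenario) pairs\n",
                nrow(x$infeasible_pairs)))
  }
  invisible(x)
}

#' Default confidence-level evaluation grid
#'
#' 0.50 to 0.95 in steps of 0.05, plus 0.98 — the range swept in the design
#' of experiments.
#' @return Numeric vector.
#' @export
default_beta_grid <- function() c(seq(0.5, 0.95, by = 0.05), 0.98)

#' Highest feasible confidence level per condition
#'
#' A confidence level is feasible for a condition when in every scenario even
#' the constraint permits some assignment, i.e. the sum over patients of each
#' patient's smallest plan mean stays within `mu_star_c(beta)` — a necessary
#' and sufficient screening that avoids full solves. The overall `beta_star`
#' is the minimum over conditions.
#'
#' @param scenarios A scenario set.
#' @param spec The matching [hospital_spec()].
#' @param beta_grid Increasing grid of candidate levels in (0, 1).
#' @return List with `per_condition` (named vector of the largest feasible
#'   grid value per condition, `NA` when even the smallest fails) and
#'   `overall` (their minimum; `NA` if any condition has none feasible).
#' @export
max_feasible_beta <- function(scenarios, spec, beta_grid = default_beta_grid()) {
  stopifnot(inherits(scenarios, "scenario_set"), inherits(spec, "hospital_spec"))
  beta_grid <- sort(as.numeric(beta_grid))
  if (!length(beta_grid) || any(beta_grid <= 0) || any(beta_grid >= 1))
    stop("max_feasible_beta: beta_grid must be a non-empty grid in (0, 1)",
         call. = FALSE)
  ids <- condition_ids(spec)
  per <- vapply(ids, function(id) {
    cs <- spec$conditions[[id]]
    cc <- scenarios$conditions[[id]]
    min_sum <- max(vapply(seq_len(scenarios$n_scenarios), function(w)
      sum(apply(cc$mu_hat[, , w, drop = FALSE], 1, min)), numeric(1)))
    ok <- vapply(beta_grid, function(b) {
      th <- deterministic_threshold(cs$target_rate, cs$n_patients, cs$lambda, b)
      min_sum <= th$mu_star + 1e-9
    }, logical(1))
    if (!any(ok)) NA_real_ else max(beta_grid[ok])
  }, numeric(1))
  names(per) <- ids
  list(per_condition = per,
       overall = if (anyNA(per)) NA_real_ else min(per))
}
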