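test_that("hand-enumerated assignment instances solve exactly", {
  # one patient: the cheap plan violates the cap, the expensive one fits
  r <- solve_condition_scenario(rbind(c(10, 5)), rbind(c(0.1, 0.3)), 0.2)
  expect_identical(r$assignment, 1L)
  expect_identical(r$total_cost, 10)
  # two identical patients, cap fits exactly one cheap plan:
  # (2,2) has mu 0.5 > 0.4; (1,1) costs 20; optimum 14, lexicographically (1,2)
  costs <- rbind(c(10, 4), c(10, 4))
  mus <- rbind(c(0.1, 0.25), c(0.1, 0.25))
  r2 <- solve_condition_scenario(costs, mus, 0.40)
  expect_identical(r2$assignment, c(1L, 2L))
  expect_identical(r2$total_cost, 14)
  b2 <- brute_force_oracle(costs, mus, 0.40)
  expect_identical(b2$assignment, r2$assignment)
  expect_identical(b2$total_cost, r2$total_cost)
  # slack cap: everyone on their cheapest plan
  r3 <- solve_condition_scenario(costs, mus, 10)
  expect_identical(r3$assignment, c(2L, 2L))
  expect_identical(r3$total_cost, 8)
  # infeasible: even the minimal means overshoot
  r4 <- solve_condition_scenario(costs, mus, 0.15)
  expect_identical(r4$status, "infeasible")
  expect_equal(r4$margin, 0.2 - 0.15)
  b4 <- brute_force_oracle(costs, mus, 0.15)
  expect_identical(b4$status, "infeasible")
  expect_equal(b4$margin, r4$margin)
})

test_that("equal-cost optima break ties toward the lowest plan indices", {
  # plans 1 and 2 cost the same; plan 1 has higher mu but still fits
  r <- solve_condition_scenario(rbind(c(10, 10, 4)), rbind(c(0.3, 0.2, 0.6)),
                                0.35)
  expect_identical(r$assignment, 1L)
  b <- brute_force_oracle(rbind(c(10, 10, 4)), rbind(c(0.3, 0.2, 0.6)), 0.35)
  expect_identical(b$assignment, 1L)
  # two patients with symmetric equal-cost optima -> (1, 2) not (2, 1)
  costs <- rbind(c(7, 3), c(7, 3))
  mus <- rbind(c(0.05, 0.2), c(0.05, 0.2))
  expect_identical(solve_condition_scenario(costs, mus, 0.25)$assignment,
                   c(1L, 2L))
  expect_identical(brute_force_oracle(costs, mus, 0.25)$assignment,
                   c(1L, 2L))
})

test_that("branch-and-bound equals exhaustive enumeration on random instances", {
  n_infeasible <- 0L
  for (seed in 1:60) {
    inst <- rand_instance(seed)
    s <- solve_condition_scenario(inst$costs, inst$mu, inst$cap)
    b <- brute_force_oracle(inst$costs, inst$mu, inst$cap)
    expect_identical(s$feasible, b$feasible, label = paste("seed", seed))
    if (s$feasible) {
      expect_identical(s$assignment, b$assignment, label = paste("seed", seed))
      expect_equal(s$total_cost, b$total_cost, tolerance = 1e-12)
    } else {
      n_infeasible <- n_infeasible + 1L
      expect_equal(s$margin, b$margin, tolerance = 1e-12)
    }
  }
  expect_gt(n_infeasible, 0L)  # the random caps do exercise both outcomes
  expect_error(brute_force_oracle(matrix(1, 15, 10), matrix(0.1, 15, 10), 1),
               "too large")
})

test_that("the full model decomposes and composes its objective", {
  # 1 condition, 1 scenario, the enumerated 2-patient instance; beta = 0.5
  # makes mu* = theta |P| = 0.40; penalty 0 -> objective 14
  spec <- hospital_spec("one", list(
    condition_spec("C1", target_rate = 0.20, hospital_mean_rate = 0.25,
                   n_patients = 2, cost_triangular = c(4, 8, 12),
                   n_plans = 2, tier_sizes = c(1, 1))), annual_penalty = 0)
  costs <- rbind(c(10, 4), c(10, 4))
  mus <- rbind(c(0.1, 0.25), c(0.1, 0.25))
  ss1 <- fake_scenario_set(spec, list(C1 = list(costs)), list(C1 = list(mus)))
  sol1 <- solve_dem(ss1, 0.5, spec)
  expect_identical(sol1$status, "solved")
  expect_equal(sol1$objective, 14)
  expect_equal(sol1$expected_penalty, 0)
  # two identical scenarios with p = 0.5 each -> same objective
  ss2 <- fake_scenario_set(spec, list(C1 = list(costs, costs)),
                           list(C1 = list(mus, mus)))
  sol2 <- solve_dem(ss2, 0.5, spec)
  expect_equal(sol2$objective, sol1$objective)
  # objective identity: expected cost + expected penalty, exactly
  spec_p <- hospital_spec("one", spec$conditions, annual_penalty = 1000)
  sol3 <- solve_dem(ss2, 0.6, spec_p)
  expect_identical(sol3$objective,
                   sol3$expected_treatment_cost + sol3$expected_penalty)
  # infeasible (c, omega) pairs are reported, not silently dropped
  sol4 <- solve_dem(ss1, 0.5,
                    hospital_spec("one", list(condition_spec(
                      "C1", 0.05, 0.25, n_patients = 2,
                      cost_triangular = c(4, 8, 12), n_plans = 2,
                      tier_sizes = c(1, 1))), 0))
  expect_identical(sol4$status, "infeasible")
  expect_identical(sol4$infeasible_pairs$condition, "C1")
})

test_that("solving scenarios independently matches a joint small solve", {
  spec <- make_tiny_spec(penalty = 0)
  ss <- generate_scenarios(spec, 3, generator_settings(seed = 21))
  sol <- solve_dem(ss, 0.7, spec)
  expect_identical(sol$status, "solved")
  # re-solve each (condition, scenario) in isolation and rebuild the objective
  total <- 0
  for (id in names(ss$conditions)) {
    cs <- spec$conditions[[id]]
    th <- deterministic_threshold(cs$target_rate, cs$n_patients, cs$lambda, 0.7)
    for (w in 1:3) {
      r <- brute_force_oracle(ss$conditions[[id]]$cost[, , w],
                              ss$conditions[[id]]$mu_hat[, , w], th$mu_star)
      total <- total + ss$p[w] * r$total_cost
    }
  }
  expect_equal(sol$expected_treatment_cost, total, tolerance = 1e-12)
})

test_that("expected cost rises and selected means fall as beta tightens", {
  spec <- make_tiny_spec(penalty = 0)
  ss <- generate_scenarios(spec, 4, generator_settings(seed = 33))
  grid <- c(0.5, 0.65, 0.8, 0.85)
  sols <- lapply(grid, function(b) solve_dem(ss, b, spec))
  expect_true(all(vapply(sols, function(s) identical(s$status, "solved"),
                         logical(1))))
  costs <- vapply(sols, `[[`, numeric(1), "expected_treatment_cost")
  expect_true(all(diff(costs) >= -1e-9))
  mus <- vapply(sols, function(s) sum(s$results$mu_sum), numeric(1))
  expect_true(all(diff(mus) <= 1e-9))
})

test_that("the feasibility frontier search matches the screening rule", {
  # 1 condition, 1 scenario, |P| = 2, per-patient min mu summing to 0.3:
  # mu*(0.5) = 0.4, mu*(0.6) ~ 0.3275, mu*(0.7) ~ 0.2650 -> beta* = 0.6
  expect_equal(mu_star_oracle(0.2, 2, 0.25, 0.6), 0.3275, tolerance = 1e-4)
  expect_equal(mu_star_oracle(0.2, 2, 0.25, 0.7), 0.2650, tolerance = 1e-4)
  spec <- hospital_spec("f", list(
    condition_spec("C1", 0.2, 0.25, n_patients = 2,
                   cost_triangular = c(4, 8, 12), n_plans = 2,
                   tier_sizes = c(1, 1))), 0)
  ss <- fake_scenario_set(spec,
                          list(C1 = list(rbind(c(9, 5), c(9, 5)))),
                          list(C1 = list(rbind(c(0.14, 0.30), c(0.16, 0.35)))))
  mb <- max_feasible_beta(ss, spec, c(0.5, 0.6, 0.7, 0.8))
  expect_equal(mb$per_condition[["C1"]], 0.6)
  expect_equal(mb$overall, 0.6)
  # all minima ~0 -> top of grid; minima above theta|P| -> none feasible
  ss_easy <- fake_scenario_set(spec,
                               list(C1 = list(rbind(c(9, 5), c(9, 5)))),
                               list(C1 = list(rbind(c(0.001, 0.3), c(0.001, 0.3)))))
  expect_equal(max_feasible_beta(ss_easy, spec, c(0.5, 0.6, 0.7, 0.8))$overall,
               0.8)
  ss_hard <- fake_scenario_set(spec,
                               list(C1 = list(rbind(c(9, 5), c(9, 5)))),
                               list(C1 = list(rbind(c(0.25, 0.3), c(0.25, 0.3)))))
  mbh <- max_feasible_beta(ss_hard, spec, c(0.5, 0.6, 0.7, 0.8))
  expect_true(is.na(mbh$per_condition[["C1"]]))
  expect_true(is.na(mbh$overall))
  # frontier property: every grid point below beta* is feasible too
  cs <- spec$conditions$C1
  for (b in c(0.5, 0.6))
    expect_lte(0.3, deterministic_threshold(0.2, 2, 0.25, b)$mu_star + 1e-9)
})
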