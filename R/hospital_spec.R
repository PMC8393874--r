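#' Define one condition of a hospital decision instance
#'
#' A condition bundles everything the model needs for one penalized diagnosis
#' group: the target readmission rate (typically the peer-group mean), the
#' hospital's own current mean readmission probability, the Gaussian variance
#' scale, the expected patient count for the decision period, the triangular
#' cost distribution of its treatment plans, and the tier structure of the
#' plans (Tier 1 = high-cost/low-readmission, last tier = low-cost/high-
#' readmission).
#'
#' All rates are probabilities on the 0-1 scale (a printed 15.97% is 0.1597).
#'
#' @param id Short condition label, e.g. `"AMI"`.
#' @param target_rate Target readmission rate theta, in (0, 1].
#' @param hospital_mean_rate The hospital's current mean readmission
#'   probability mu, in (0, 1).
#' @param lambda Variance scale of the Gaussian readmission model (the
#'   per-patient readmission mean is N(mu, lambda * mu), variance
#'   `lambda * mu`). Positive; default 0.25.
#' @param n_patients Expected number of patients in the decision period.
#' @param cost_triangular Numeric triple `c(min, mode, max)` of the triangular
#'   treatment-plan cost distribution, USD.
#' @param n_plans Number of treatment plans per patient; default 10.
#' @param tier_sizes Ordered plan counts per tier, summing to `n_plans`.
#'   Defaults to `c(3, 4, 3)` when `n_plans` is 10.
#' @return An object of class `condition_spec`.
#' @export
#' @examples
#' condition_spec("AMI", target_rate = 0.1597, hospital_mean_rate = 0.2121,
#'                n_patients = 52, cost_triangular = c(6745, 8431, 21078))
condition_spec <- function(id, target_rate, hospital_mean_rate,
                           lambda = 0.25, n_patients, cost_triangular,
                           n_plans = 10L, tier_sizes = NULL) {
  if (is.null(tier_sizes)) {
    if (identical(as.integer(n_plans), 10L)) tier_sizes <- c(3L, 4L, 3L)
    else tier_sizes <- as.integer(n_plans)  # single tier fallback
  }
  x <- structure(list(
    id = as.character(id),
    target_rate = as.numeric(target_rate),
    hospital_mean_rate = as.numeric(hospital_mean_rate),
    lambda = as.numeric(lambda),
    n_patients = as.numeric(n_patients),
    cost_triangular = as.numeric(cost_triangular),
    n_plans = as.numeric(n_plans),
    tier_sizes = as.numeric(tier_sizes)
  ), class = "condition_spec")
  problems <- validate_condition_spec(x)
  if (length(problems)) fail_validation(problems, sprintf("condition '%s'", id))
  x$n_patients <- as.integer(x$n_patients)
  x$n_plans <- as.integer(x$n_plans)
  x$tier_sizes <- as.integer(x$tier_sizes)
  x
}

validate_condition_spec <- function(x) {
  p <- character()
  if (!length(x$id) || is.na(x$id) || !nzchar(x$id)) p <- c(p, "id: must be a non-empty label")
  if (!is_prob(x$target_rate) || x$target_rate <= 0 || x$target_rate > 1)
    p <- c(p, sprintf("target_rate: must be in (0, 1], got %s", format(x$target_rate)))
  if (!is_prob(x$hospital_mean_rate) || x$hospital_mean_rate <= 0 || x$hospital_mean_rate >= 1)
    p <- c(p, sprintf("hospital_mean_rate: must be in (0, 1), got %s", format(x$hospital_mean_rate)))
  if (!is_prob(x$lambda) || x$lambda <= 0)
    p <- c(p, sprintf("lambda: must be > 0, got %s", format(x$lambda)))
  if (!is_count(x$n_patients))
    p <- c(p, "n_patients: must be a positive integer")
  tri <- x$cost_triangular
  if (length(tri) != 3L || anyNA(tri) || !is.numeric(tri)) {
    p <- c(p, "cost_triangular: must be a numeric triple (min, mode, max)")
  } else {
    if (!(tri[1] <= tri[2] && tri[2] <= tri[3]))
      p <- c(p, "cost_triangular: requires min <= mode <= max")
    if (tri[1] < 0) p <- c(p, "cost_triangular: costs must be non-negative")
  }
  if (!is_count(x$n_plans)) p <- c(p, "n_plans: must be a positive integer")
  if (anyNA(x$tier_sizes) || any(x$tier_sizes < 1) ||
      any(x$tier_sizes != floor(x$tier_sizes)))
    p <- c(p, "tier_sizes: entries must be positive integers")
  else if (is_count(x$n_plans) && sum(x$tier_sizes) != x$n_plans)
    p <- c(p, sprintf("tier_sizes: must sum to n_plans (%d), got %d",
                      x$n_plans, sum(x$tier_sizes)))
  p
}

#' Assemble a hospital decision instance
#'
#' @param hospital_id Hospital label.
#' @param conditions List of [condition_spec()] objects with unique ids.
#' @param annual_penalty The hospital's one-year penalty cost in USD
#'   (non-negative). Passed through to the expected-penalty model unmodified;
#'   it is not prorated to the decision period.
#' @param decision_period Informational label; default `"3 months"`.
#' @return An object of class `hospital_spec`.
#' @seealso [load_hospital_spec()], [example_hospital_spec()]
#' @export
hospital_spec <- function(hospital_id, conditions, annual_penalty,
                          decision_period = "3 months") {
  x <- structure(list(
    hospital_id = as.character(hospital_id),
    conditions = conditions,
    annual_penalty = as.numeric(annual_penalty),
    decision_period = as.character(decision_period)
  ), class = "hospital_spec")
  problems <- validate_hospital_spec(x)
  if (length(problems)) fail_validation(problems, sprintf("hospital spec '%s'", hospital_id))
  names(x$conditions) <- condition_ids(x)
  x
}

validate_hospital_spec <- function(x) {
  p <- character()
  if (!length(x$conditions)) p <- c(p, "conditions: must be non-empty")
  if (!all(vapply(x$conditions, inherits, logical(1), "condition_spec")))
    p <- c(p, "conditions: every entry must be a condition_spec")
  else {
    ids <- vapply(x$conditions, `[[`, character(1), "id")
    if (anyDuplicated(ids)) p <- c(p, "conditions: condition ids must be unique")
    p <- c(p, unlist(lapply(x$conditions, validate_condition_spec)))
  }
  if (!is_prob(x$annual_penalty) || x$annual_penalty < 0)
    p <- c(p, "annual_penalty: must be a non-negative USD amount")
  p
}

condition_ids <- function(spec) vapply(spec$conditions, `[[`, character(1), "id")

#' @export
print.hospital_spec <- function(x, ...) {
  cat(sprintf("<hospital_spec> %s  (%d conditions, penalty $%s, period: %s)\n",
              x$hospital_id, length(x$conditions),
              format(x$annual_penalty, big.mark = ","), x$decision_period))
  for (cs in x$conditions) {
    cat(sprintf("  %-5s theta=%.4f mu=%.4f lambda=%.2f |P|=%3d plans=%d tiers=(%s) TRIA(%s)\n",
                cs$id, cs$target_rate, cs$hospital_mean_rate, cs$lambda,
                cs$n_patients, cs$n_plans, paste(cs$tier_sizes, collapse = ","),
                paste(format(cs$cost_triangular, trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}

#' Read a hospital specification from YAML
#'
#' The schema is a mapping with keys `hospital_id`, `annual_penalty`,
#' optionally `decision_period`, and `conditions`: a sequence of mappings with
#' keys `id`, `target_rate`, `hospital_mean_rate`, `lambda` (optional, default
#' 0.25), `n_patients`, `cost_triangular` (3-element sequence), `n_plans`
#' (optional, default 10) and `tier_sizes` (optional, default 3/4/3 for 10
#' plans). Rates are probabilities on the 0-1 scale.
#'
#' @param source Path to a YAML file, or a YAML string.
#' @return A validated [hospital_spec()].
#' @export
load_hospital_spec <- function(source) {
  txt <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else source
  raw <- tryCatch(yaml::yaml.load(txt),
                  error = function(e) stop("hospital spec: YAML parse failure: ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("hospital_id", "annual_penalty", "conditions"))
    if (is.null(raw[[key]]))
      stop(sprintf("hospital spec: missing required key '%s'", key), call. = FALSE)
  conds <- lapply(raw$conditions, function(cc) {
    for (key in c("id", "target_rate", "hospital_mean_rate", "n_patients",
                  "cost_triangular"))
      if (is.null(cc[[key]]))
        stop(sprintf("hospital spec: condition entry missing required key '%s'", key),
             call. = FALSE)
    condition_spec(
      id = cc$id, target_rate = cc$target_rate,
      hospital_mean_rate = cc$hospital_mean_rate,
      lambda = cc$lambda %||% 0.25,
      n_patients = cc$n_patients,
      cost_triangular = unlist(cc$cost_triangular),
      n_plans = cc$n_plans %||% 10L,
      tier_sizes = if (is.null(cc$tier_sizes)) NULL else unlist(cc$tier_sizes)
    )
  })
  hospital_spec(raw$hospital_id, conds, raw$annual_penalty,
                raw$decision_period %||% "3 months")
}

#' Write a hospital specification as YAML
#'
#' Emits text that [load_hospital_spec()] parses back to an equal spec.
#'
#' @param spec A [hospital_spec()].
#' @param path Optional file path; when given the YAML is also written there.
#' @return The YAML text, invisibly when `path` is given.
#' @export
write_hospital_spec <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "hospital_spec"))
  obj <- list(
    hospital_id = spec$hospital_id,
    annual_penalty = spec$annual_penalty,
    decision_period = spec$decision_period,
    conditions = lapply(unname(spec$conditions), function(cs) list(
      id = cs$id, target_rate = cs$target_rate,
      hospital_mean_rate = cs$hospital_mean_rate, lambda = cs$lambda,
      n_patients = cs$n_patients, cost_triangular = as.list(cs$cost_triangular),
      n_plans = cs$n_plans, tier_sizes = as.list(cs$tier_sizes)
    ))
  )
  txt <- yaml::as.yaml(obj, precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Packaged example hospital instances
#'
#' Two peer-group-2 hospital instances at desk scale: `"A"`, a low-performing
#' hospital (five of six conditions above their peer-group-mean targets,
#' cumulative 1.35% penalty in the source data) and `"B"`, a high-performing
#' hospital (one exceedance, 0.2% penalty). Targets are the peer-group-2 mean
#' readmission probabilities; patient counts are three-month volumes; plan
#' costs are triangular (low / fair / high price). The annual dollar penalty
#' is not published for these hospitals, so the packaged files carry a
#' round-number placeholder that users should replace with their own figure.
#'
#' @param which `"A"` or `"B"`.
#' @return A [hospital_spec()].
#' @export
#' @examples
#' example_hospital_spec("A")
example_hospital_spec <- function(which = c("A", "B")) {
  which <- match.arg(which)
  path <- system.file("extdata", sprintf("hospital_%s.yaml", which),
                      package = "readmitopt", mustWork = TRUE)
  load_hospital_spec(path)
}

#' Conditions whose current mean exceeds the target
#'
#' A condition draws a penalty when the hospital's mean readmission
#' probability is strictly greater than the target (peer-group mean) rate.
#'
#' @param spec A [hospital_spec()].
#' @return Character vector of penalized condition ids.
#' @export
penalized_conditions <- function(spec) {
  stopifnot(inherits(spec, "hospital_spec"))
  ids <- condition_ids(spec)
  exceed <- vapply(spec$conditions,
                   function(cs) cs$hospital_mean_rate > cs$target_rate,
                   logical(1))
  unname(ids[exceed])
}

#' Build a per-condition confidence-level vector
#'
#' @param spec A [hospital_spec()].
#' @param beta A single confidence level recycled to every condition, or a
#'   vector (optionally named by condition id) with one entry per condition.
#'   Every entry must lie strictly in (0, 1).
#' @return Named numeric vector, one entry per condition in spec order.
#' @export
beta_vector <- function(spec, beta) {
  stopifnot(inherits(spec, "hospital_spec"))
  ids <- condition_ids(spec)
  if (length(beta) == 1L) beta <- rep(beta, length(ids))
  if (!is.null(names(beta))) {
    if (!setequal(names(beta), ids))
      stop("beta_vector: names must match the spec's condition ids", call. = FALSE)
    beta <- beta[ids]
  }
  if (length(beta) != length(ids))
    stop("beta_vector: need one confidence level per condition", call. = FALSE)
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("beta_vector: confidence levels must lie strictly in (0, 1)", call. = FALSE)
  stats::setNames(as.numeric(beta), ids)
}
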