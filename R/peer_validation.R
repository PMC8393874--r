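#' Validate and class a peer-group record table
#'
#' Records follow the public HRRP supplemental-file layout: one row per
#' (hospital, condition) with the peer group (1-5), the excess readmission
#' ratio (ERR), the hospital's readmission probability for the condition, and
#' the number of eligible cases.
#'
#' @param df Data frame with columns `hospital_id`, `peer_group`,
#'   `condition`, `err`, `readmission_prob`, `cases`.
#' @return The validated data frame with class `peer_record_table`.
#' @export
peer_record_table <- function(df) {
  req <- c("hospital_id", "peer_group", "condition", "err",
           "readmission_prob", "cases")
  missing_cols <- setdiff(req, names(df))
  p <- character()
  if (length(missing_cols))
    p <- c(p, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  else {
    if (any(!is.finite(df$err)) || any(df$err <= 0))
      p <- c(p, "err: must be positive")
    if (any(!is.finite(df$readmission_prob)) ||
        any(df$readmission_prob <= 0) || any(df$readmission_prob >= 1))
      p <- c(p, "readmission_prob: must lie in (0, 1)")
    if (any(!df$peer_group %in% 1:5))
      p <- c(p, "peer_group: must be in 1..5")
    if (any(!is.finite(df$cases)) || any(df$cases < 0))
      p <- c(p, "cases: must be non-negative")
    if (anyDuplicated(df[c("hospital_id", "condition")]))
      p <- c(p, "duplicate (hospital_id, condition) rows")
  }
  if (length(p)) fail_validation(p, "peer record table")
  structure(df, class = c("peer_record_table", "data.frame"))
}

#' Label records as penalized (actual) and flagged (predicted)
#'
#' Within each (peer group, condition) stratum, the *actual* flag reproduces
#' the penalty rule — ERR strictly greater than the stratum's median ERR —
#' and the *predicted* flag applies the candidate target — readmission
#' probability strictly greater than the stratum's mean probability
#' (case-weighted when `case_weighted = TRUE`). Records exactly at the
#' threshold are not flagged. Strata with fewer than two records are
#' excluded; they are listed in the `excluded_strata` attribute.
#'
#' @param table A [peer_record_table()].
#' @param case_weighted Weight the stratum mean probability by eligible
#'   cases; default unweighted.
#' @return The included rows with logical columns `actual` and `predicted`;
#'   attribute `excluded_strata` holds any dropped (peer_group, condition)
#'   pairs.
#' @export
label_records <- function(table, case_weighted = FALSE) {
  if (!inherits(table, "peer_record_table")) table <- peer_record_table(table)
  if (!nrow(table)) stop("label_records: empty table", call. = FALSE)
  key <- interaction(table$peer_group, table$condition, drop = TRUE)
  parts <- split(seq_len(nrow(table)), key)
  small <- vapply(parts, length, integer(1)) < 2L
  excluded <- do.call(rbind, lapply(parts[small], function(ix)
    unique(data.frame(peer_group = table$peer_group[ix],
                      condition = table$condition[ix]))))
  keep <- unlist(parts[!small], use.names = FALSE)
  out <- table[keep, , drop = FALSE]
  class(out) <- "data.frame"
  grp <- interaction(out$peer_group, out$condition, drop = TRUE)
  med_err <- stats::ave(out$err, grp, FUN = stats::median)
  mean_prob <- if (case_weighted) {
    stats::ave(seq_len(nrow(out)), grp, FUN = function(ix)
      stats::weighted.mean(out$readmission_prob[ix], out$cases[ix]))
  } else {
    stats::ave(out$readmission_prob, grp, FUN = mean)
  }
  out$actual <- out$err > med_err
  out$predicted <- out$readmission_prob > mean_prob
  attr(out, "excluded_strata") <-
    if (is.null(excluded)) data.frame(peer_group = integer(), condition = character())
    else excluded
  out
}

#' Confusion-matrix summary per peer group
#'
#' Pools the labelled records per peer group (across conditions) and counts
#' true/false positives/negatives of the predicted measure against the
#' actual penalty rule. Accuracy is `(TP + TN) / N * 100`; the
#' misclassification rate is its exact complement.
#'
#' @param labeled Output of [label_records()].
#' @return An object of class `confusion_summary`: data frame with columns
#'   `peer_group`, `n`, `TP`, `FP`, `FN`, `TN`, `accuracy_pct`,
#'   `misclassification_pct`.
#' @export
confusion_summary <- function(labeled) {
  if (!all(c("actual", "predicted") %in% names(labeled)))
    stop("confusion_summary: expected a label_records() result", call. = FALSE)
  groups <- sort(unique(labeled$peer_group))
  rows <- lapply(groups, function(g) {
    d <- labeled[labeled$peer_group == g, ]
    tp <- sum(d$actual & d$predicted)
    fp <- sum(!d$actual & d$predicted)
    fn <- sum(d$actual & !d$predicted)
    tn <- sum(!d$actual & !d$predicted)
    acc <- 100 * (tp + tn) / nrow(d)
    data.frame(peer_group = g, n = nrow(d), TP = tp, FP = fp, FN = fn, TN = tn,
               accuracy_pct = acc, misclassification_pct = 100 - acc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confusion_summary", class(out))
  out
}

#' Generate synthetic peer-group records
#'
#' A stand-in for the public HRRP supplemental download, for testing the
#' target-validation analysis without external data. Per (peer group,
#' condition) stratum it draws a latent Gaussian score per hospital, maps it
#' to a lognormal ERR centred at 1, and couples the readmission probability
#' through a Gaussian copula with correlation `rho` (an affine link around a
#' condition-typical rate). Latent draws are antithetic (sign-symmetrized)
#' within each stratum, so the sample mean of the probability column sits
#' exactly at the stratum centre; under a perfectly monotone link
#' (`rho = 1`) the strict mean-split of probabilities then coincides with
#' the strict median-split of ERR and the confusion matrix is exact.
#'
#' @param n_hospitals Hospitals per peer group (single value or length-5
#'   vector); an even number, at least 2 (the latent draws come in
#'   antithetic pairs).
#' @param conditions Condition ids; default the six HRRP conditions.
#' @param rho Latent correlation between ERR and readmission probability,
#'   in `[-1, 1]`.
#' @param seed RNG seed.
#' @param err_sdlog Log-scale spread of ERR around 1.
#' @param prob_centers Named (or recycled) typical readmission probabilities
#'   per condition.
#' @param prob_scale Relative spread of the probability column: its standard
#'   deviation is `prob_scale` times the condition centre, with the latent
#'   score clamped symmetrically at +/- 3 so probabilities always stay
#'   strictly inside (0, 1) (no asymmetric clipping).
#' @return A [peer_record_table()].
#' @export
synth_peer_records <- function(n_hospitals, conditions = c("AMI", "PN", "HF",
                                                           "HK", "COPD", "CABG"),
                               rho = 0.8, seed = 1L, err_sdlog = 0.1,
                               prob_centers = c(AMI = 0.16, PN = 0.15,
                                                HF = 0.20, HK = 0.08,
                                                COPD = 0.19, CABG = 0.15),
                               prob_scale = 0.2) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < -1 || rho > 1)
    stop("synth_peer_records: rho must lie in [-1, 1]", call. = FALSE)
  n_hospitals <- rep_len(as.integer(n_hospitals), 5L)
  if (any(n_hospitals < 2L))
    stop("synth_peer_records: need at least 2 hospitals per peer group",
         call. = FALSE)
  if (any(n_hospitals %% 2L != 0L))
    stop("synth_peer_records: hospital counts must be even (draws are antithetic pairs)",
         call. = FALSE)
  if (is.null(names(prob_centers)))
    prob_centers <- stats::setNames(rep_len(prob_centers, length(conditions)),
                                    conditions)
  sym_normal <- function(n) {
    h <- stats::rnorm(n / 2)
    c(h, -h)
  }
  with_seed(seed, {
    rows <- list()
    for (g in 1:5) {
      ids <- sprintf("H%d_%03d", g, seq_len(n_hospitals[g]))
      for (cond in conditions) {
        n <- n_hospitals[g]
        z1 <- sym_normal(n)
        e <- sym_normal(n)
        z2 <- clip(rho * z1 + sqrt(1 - rho^2) * e, -3, 3)
        ctr <- prob_centers[[cond]]
        prob <- ctr * (1 + prob_scale * z2)
        rows[[length(rows) + 1L]] <- data.frame(
          hospital_id = ids, peer_group = g, condition = cond,
          err = exp(err_sdlog * z1), readmission_prob = prob,
          cases = 25L + stats::rpois(n, 75))
      }
    }
    peer_record_table(do.call(rbind, rows))
  })
}

#' Read / write peer records and confusion summaries as CSV
#'
#' @param path CSV path.
#' @return `read_peer_records` returns a [peer_record_table()].
#' @export
read_peer_records <- function(path) {
  peer_record_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_peer_records
#' @param table A peer record table to write.
#' @export
write_peer_records <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
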