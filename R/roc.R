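#' ROC area under the curve
#'
#' AUC computed as the Mann-Whitney U statistic normalized by `n1 * n2`, with
#' half credit for ties. The orientation is chosen so that the reported AUC is
#' at least 0.5, and the favored direction is recorded.
#'
#' @param case_values,control_values Numeric vectors with at least 2 values
#'   each.
#' @return A list with `auc` (oriented, >= 0.5), `auc_raw` (probability a
#'   random case exceeds a random control), `direction` (`"case_higher"` or
#'   `"control_higher"`) and `degenerate` (TRUE when all values are
#'   identical).
#' @examples
#' roc_auc(c(2, 3), 1)$auc
#' @export
roc_auc <- function(case_values, control_values) {
  n1 <- length(case_values); n0 <- length(control_values)
  stopifnot(n1 >= 1, n0 >= 1, all(is.finite(case_values)),
            all(is.finite(control_values)))
  r <- rank(c(case_values, control_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc_raw <- u / (n1 * n0)
  degenerate <- length(unique(c(case_values, control_values))) == 1L
  if (auc_raw >= 0.5)
    list(auc = auc_raw, auc_raw = auc_raw, direction = "case_higher",
         degenerate = degenerate)
  else
    list(auc = 1 - auc_raw, auc_raw = auc_raw, direction = "control_higher",
         degenerate = degenerate)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-theory interval using the DeLong placement-variance estimate,
#' truncated to \[0, 1\]. When the placement variance is exactly zero (e.g.
#' perfect separation) a stratified bootstrap (2000 resamples, seeded)
#' percentile interval is used instead.
#'
#' @param case_values,control_values Numeric vectors (>= 2 each).
#' @param level Confidence level (default 0.95).
#' @param boot_seed Seed for the bootstrap fallback.
#' @return A list with `ci_low`, `ci_high`, `method` (`"delong"` or
#'   `"bootstrap"`).
#' @export
auc_ci <- function(case_values, control_values, level = 0.95, boot_seed = 1L) {
  n1 <- length(case_values); n0 <- length(control_values)
  stopifnot(n1 >= 2, n0 >= 2, level > 0, level < 1)
  auc <- roc_auc(case_values, control_values)$auc
  oriented_case <- if (roc_auc(case_values, control_values)$direction ==
                       "case_higher") case_values else -case_values
  oriented_ctrl <- if (roc_auc(case_values, control_values)$direction ==
                       "case_higher") control_values else -control_values
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(oriented_case, function(a) mean(psi(a, oriented_ctrl)), numeric(1))
  v01 <- vapply(oriented_ctrl, function(b) mean(psi(oriented_case, b)), numeric(1))
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (v > 0) {
    lo <- max(0, auc - z * sqrt(v)); hi <- min(1, auc + z * sqrt(v))
    return(list(ci_low = lo, ci_high = hi, method = "delong"))
  }
  set.seed(as.integer(boot_seed))
  b <- replicate(2000, {
    roc_auc(sample(oriented_case, n1, replace = TRUE),
            sample(oriented_ctrl, n0, replace = TRUE))$auc_raw
  })
  q <- stats::quantile(b, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(ci_low = max(0, min(q[1], auc)), ci_high = min(1, max(q[2], auc)),
       method = "bootstrap")
}

#' Youden-optimal classification threshold
#'
#' Exhaustive scan over the midpoints between consecutive distinct pooled
#' values (with infinite sentinels), maximizing Youden's
#' `J = sensitivity + specificity - 1`. Ties are broken by higher sensitivity,
#' then by lower threshold. A sample is called positive when its value lies on
#' the case side of the threshold (above it when cases run higher, below it
#' otherwise).
#'
#' @param case_values,control_values Numeric vectors (>= 2 each).
#' @return A list with `threshold`, `sensitivity`, `specificity`, `J`,
#'   `direction`.
#' @examples
#' youden_threshold(c(3, 4), c(1, 2)) # J = 1 at threshold 2.5
#' @export
youden_threshold <- function(case_values, control_values) {
  stopifnot(length(case_values) >= 2, length(control_values) >= 2)
  dir <- roc_auc(case_values, control_values)$direction
  v <- sort(unique(c(case_values, control_values)))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best <- NULL
  for (thr in cand) {
    if (dir == "case_higher") {
      sens <- mean(case_values > thr); spec <- mean(control_values <= thr)
    } else {
      sens <- mean(case_values < thr); spec <- mean(control_values >= thr)
    }
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 && thr < best$threshold))))
      best <- list(threshold = thr, sensitivity = sens, specificity = spec,
                   J = J, direction = dir)
  }
  best
}

#' ROC report for a set of candidate features
#'
#' Computes AUC, DeLong 95% confidence interval, Youden-optimal threshold and
#' the attained sensitivity/specificity for each feature of a cohort.
#'
#' @param cohort A `lipid_cohort` (abundance matrix + group factor).
#' @param features Character vector of feature (column) names; default all.
#' @param level Confidence level (default 0.95).
#' @return A data frame with one row per feature: `feature_id`, `auc`,
#'   `ci_low`, `ci_high`, `threshold`, `sensitivity`, `specificity`,
#'   `direction`, ordered by `auc` descending.
#' @export
roc_report <- function(cohort, features = colnames(cohort$abundance),
                       level = 0.95) {
  ab <- cohort$abundance; grp <- cohort$group
  stopifnot(all(features %in% colnames(ab)))
  rows <- lapply(features, function(f) {
    ca <- ab[grp == "case", f]; co <- ab[grp == "control", f]
    a <- roc_auc(ca, co)
    ci <- auc_ci(ca, co, level = level)
    yj <- youden_threshold(ca, co)
    data.frame(feature_id = f, auc = a$auc, ci_low = ci$ci_low,
               ci_high = ci$ci_high, threshold = yj$threshold,
               sensitivity = yj$sensitivity, specificity = yj$specificity,
               direction = a$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  out
}

#' Screen biomarker candidates against performance gates
#'
#' Keeps features that *strictly* exceed all three gates (default
#' AUC > 0.80, sensitivity > 0.70, specificity > 0.80), ordered by AUC
#' descending.
#'
#' @param reports A data frame from [roc_report()].
#' @param auc_min,sens_min,spec_min The three gates.
#' @return The passing rows of `reports`.
#' @export
screen_biomarkers <- function(reports, auc_min = 0.80, sens_min = 0.70,
                              spec_min = 0.80) {
  stopifnot(all(c("auc", "sensitivity", "specificity") %in% names(reports)))
  keep <- reports$auc > auc_min & reports$sensitivity > sens_min &
    reports$specificity > spec_min
  out <- reports[keep, , drop = FALSE]
  out <- out[order(-out$auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
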