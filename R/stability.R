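#' Ensemble-importance backend based on extremely randomized trees
#'
#' Returns a backend function for [shadow_run()]: given a feature matrix, a
#' binary factor and a seed it fits a `ranger` forest (extratrees split rule,
#' permutation importance, single thread for reproducibility) and returns the
#' named importance vector.
#'
#' @param num.trees Number of trees (default 200).
#' @param ... Further arguments passed to [ranger::ranger()].
#' @return A function `(X, y, seed) -> named numeric`.
#' @export
ranger_backend <- function(num.trees = 200, ...) {
  function(X, y, seed) {
    fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = num.trees,
                          importance = "permutation", splitrule = "extratrees",
                          num.threads = 1, seed = seed,
                          write.forest = FALSE, ...)
    fit$variable.importance
  }
}

#' Shadow-attribute feature selection (single run)
#'
#' Boruta-style iterative selection. Each iteration (1) appends one permuted
#' shadow copy of every undecided feature (padded to at least `min_shadow`
#' shadows), (2) obtains ensemble importances from the backend, (3) scores a
#' *hit* for every undecided feature whose importance exceeds the maximum
#' shadow importance of that iteration, and (4) from iteration 5 onwards
#' applies a two-sided binomial test of the hit count against
#' `Binomial(iterations, 0.5)`: significantly more hits than half confirms a
#' feature, significantly fewer rejects it (rejected features are removed
#' from the model). With `mc_adjust = TRUE` (the default, mirroring the
#' widely used R implementation of shadow selection) the threshold is
#' Bonferroni adjusted by the number of features still undecided. The loop
#' stops when all features are decided or after `max_iter` iterations;
#' undecided features remain `tentative`.
#'
#' Being an all-relevant selector, the procedure confirms *any* feature
#' carrying signal in the realized sample -- including chance associations,
#' which at small n with a hundred-plus candidates are sometimes strong.
#' `shadow_pool = "all"` keeps the shadow bar at full width for a stricter
#' null reference; see the methods vignette for the trade-off.
#'
#' @param X Numeric feature matrix (samples x features), no missing values.
#' @param y Binary factor of group labels.
#' @param seed Integer seed (all permutations and backend fits derive from it).
#' @param max_iter Maximum number of iterations (default 100).
#' @param p_threshold Binomial-test significance threshold (default 0.01).
#' @param mc_adjust Bonferroni-adjust the binomial test across the undecided
#'   features (default TRUE).
#' @param shadow_pool Which features contribute permuted shadow copies each
#'   iteration: `"nonrejected"` (default; confirmed + undecided, the canonical
#'   scheme), `"all"` (every original feature, keeping the null reference bar
#'   at full strength throughout -- stricter null calibration, lower power on
#'   weak effects), or `"undecided"` (tentative features only).
#' @param backend Importance provider, e.g. [ranger_backend()].
#' @param min_shadow Minimum number of shadow attributes per iteration.
#' @return A list of class `shadow_run`: `decision` (named factor
#'   confirmed/rejected/tentative), `hits`, `tested_iters` (iterations each
#'   feature was in the model), `importance_history` (iterations x features,
#'   NA after removal), `shadow_max`, `shadow_mean` (per iteration),
#'   `n_iter`, `seed`.
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- matrix(rnorm(40 * 10), 40, 10,
#'             dimnames = list(NULL, paste0("f", 1:10)))
#' y <- factor(rep(c("case", "control"), each = 20))
#' X[, 1] <- as.integer(y == "case") + rnorm(40, sd = 0.1)
#' shadow_run(X, y, seed = 1)$decision[1]
#' }
#' @export
shadow_run <- function(X, y, seed, max_iter = 100, p_threshold = 0.01,
                       backend = ranger_backend(), min_shadow = 5L,
                       mc_adjust = TRUE,
                       shadow_pool = c("nonrejected", "all", "undecided")) {
  shadow_pool <- match.arg(shadow_pool)
  stopifnot(is.matrix(X), is.numeric(X), !anyNA(X))
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("group labels must be binary", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  feats <- colnames(X)
  p <- length(feats)

  decision <- stats::setNames(rep("tentative", p), feats)
  hits <- stats::setNames(integer(p), feats)
  tested <- stats::setNames(integer(p), feats)
  imp_hist <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, feats))
  sh_max <- sh_mean <- rep(NA_real_, max_iter)

  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("constant feature table: all features rejected", call. = FALSE)
    decision[] <- "rejected"
    return(structure(list(decision = factor(decision,
                            levels = c("confirmed", "rejected", "tentative")),
                          hits = hits, tested_iters = tested,
                          importance_history = imp_hist[0, , drop = FALSE],
                          shadow_max = numeric(0), shadow_mean = numeric(0),
                          n_iter = 0L, seed = seed), class = "shadow_run"))
  }

  set.seed(as.integer(seed))
  n <- nrow(X)
  it <- 0L
  while (it < max_iter && any(decision == "tentative")) {
    it <- it + 1L
    undec <- feats[decision == "tentative"]
    inmodel <- feats[decision != "rejected"]

    src <- switch(shadow_pool, all = feats, nonrejected = inmodel,
                  undecided = undec)
    while (length(src) < min_shadow) src <- c(src, src)
    shadows <- sapply(src, function(f) X[sample.int(n), f])
    colnames(shadows) <- sprintf(".shadow%03d", seq_along(src))
    design <- cbind(X[, inmodel, drop = FALSE], shadows)

    bseed <- sample.int(.Machine$integer.max - 1L, 1L)
    imp <- backend(design, y, bseed)
    s_imp <- imp[colnames(shadows)]
    r_imp <- imp[inmodel]
    sh_max[it] <- max(s_imp)
    sh_mean[it] <- mean(s_imp)
    imp_hist[it, inmodel] <- r_imp

    hits[undec] <- hits[undec] + as.integer(r_imp[undec] > sh_max[it])
    tested[inmodel] <- tested[inmodel] + 1L

    if (it >= 5L) {
      thr <- if (mc_adjust) p_threshold / length(undec) else p_threshold
      for (f in undec) {
        h <- hits[f]; t <- tested[f]
        p2 <- min(1, 2 * min(stats::pbinom(h, t, 0.5),
                             stats::pbinom(h - 1L, t, 0.5, lower.tail = FALSE)))
        if (p2 < thr)
          decision[f] <- if (h > t / 2) "confirmed" else "rejected"
      }
    }
  }

  structure(list(decision = factor(decision,
                   levels = c("confirmed", "rejected", "tentative")),
                 hits = hits, tested_iters = tested,
                 importance_history = imp_hist[seq_len(it), , drop = FALSE],
                 shadow_max = sh_max[seq_len(it)],
                 shadow_mean = sh_mean[seq_len(it)],
                 n_iter = it, seed = as.integer(seed)),
            class = "shadow_run")
}

#' @export
print.shadow_run <- function(x, ...) {
  cat(sprintf("<shadow_run> %d iterations: %d confirmed, %d rejected, %d tentative\n",
              x$n_iter, sum(x$decision == "confirmed"),
              sum(x$decision == "rejected"), sum(x$decision == "tentative")))
  invisible(x)
}

# per-run summaries used by the stability aggregation: a feature's mean
# importance over the iterations it was in the model, and the run-level mean
# of the per-iteration shadow statistics
.run_summary <- function(run) {
  imp <- colMeans(run$importance_history, na.rm = TRUE)
  imp[is.nan(imp)] <- NA_real_
  list(confirmed = names(run$decision)[run$decision == "confirmed"],
       mean_imp = imp,
       shadow_max = mean(run$shadow_max),
       shadow_mean = mean(run$shadow_mean))
}

#' Two-condition resampling stability protocol
#'
#' Runs [shadow_run()] `R1` times on stratified subsamples (a
#' `subsample_fraction` share of each group, rounded half-up) and `R2` times
#' on the full data, each with a distinct seed derived from `base_seed`. A
#' feature is *stable* when it is confirmed in more than half of the runs in
#' **both** conditions. `medianImp` is the median, across all runs (both
#' conditions) in which the feature was confirmed, of its per-run mean
#' importance; shadow ratios divide `medianImp` by the median over all runs
#' of the per-run shadow maximum / mean. Tentative decisions count as not
#' confirmed.
#'
#' @param X,y,backend,max_iter,p_threshold,mc_adjust,shadow_pool As in
#'   [shadow_run()].
#' @param R1,R2 Number of subsample and full-data runs (defaults 100).
#' @param subsample_fraction Per-group subsampling fraction (default 0.70).
#' @param base_seed Integer seed for the whole protocol.
#' @return A list of class `lipid_stability` with `table` (per feature:
#'   `feature`, `confirmed_count_subsample`, `confirmed_count_full`, `stable`,
#'   `medianImp`, `ratio_to_shadow_max`, `ratio_to_shadow_mean`, `rank`),
#'   `R1`, `R2`, `shadow_max_median`, `shadow_mean_median`, `base_seed`.
#' @export
stability_protocol <- function(X, y, R1 = 100, R2 = 100,
                               subsample_fraction = 0.70, base_seed = 1L,
                               backend = ranger_backend(), max_iter = 100,
                               p_threshold = 0.01, mc_adjust = TRUE,
                               shadow_pool = c("nonrejected", "all",
                                               "undecided")) {
  shadow_pool <- match.arg(shadow_pool)
  stopifnot(is.matrix(X), R1 >= 1, R2 >= 1,
            subsample_fraction > 0, subsample_fraction <= 1)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("group labels must be binary", call. = FALSE)
  take <- vapply(levels(y), function(l)
    as.integer(floor(sum(y == l) * subsample_fraction + 0.5)), integer(1))
  if (any(take < 2L))
    stop("subsample would leave fewer than 2 samples in a group", call. = FALSE)

  base_seed <- as.integer(base_seed)
  runs <- vector("list", R1 + R2)
  for (r in seq_len(R1)) {
    seed_r <- base_seed + r
    set.seed(seed_r)
    idx <- unlist(lapply(levels(y), function(l)
      sample(which(y == l), take[[l]])))
    runs[[r]] <- .run_summary(shadow_run(X[idx, , drop = FALSE], y[idx],
                                         seed = seed_r, max_iter = max_iter,
                                         p_threshold = p_threshold,
                                         backend = backend,
                                         mc_adjust = mc_adjust,
                                         shadow_pool = shadow_pool))
  }
  for (r in seq_len(R2)) {
    seed_r <- base_seed + 100000L + r
    runs[[R1 + r]] <- .run_summary(shadow_run(X, y, seed = seed_r,
                                              max_iter = max_iter,
                                              p_threshold = p_threshold,
                                              backend = backend,
                                              mc_adjust = mc_adjust,
                                              shadow_pool = shadow_pool))
  }

  feats <- colnames(X)
  conf1 <- vapply(feats, function(f)
    sum(vapply(runs[seq_len(R1)], function(r) f %in% r$confirmed, logical(1))),
    integer(1))
  conf2 <- vapply(feats, function(f)
    sum(vapply(runs[R1 + seq_len(R2)], function(r) f %in% r$confirmed, logical(1))),
    integer(1))
  med_imp <- vapply(feats, function(f) {
    v <- unlist(lapply(runs, function(r)
      if (f %in% r$confirmed) r$mean_imp[[f]] else NULL))
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))

  shmax_med <- stats::median(vapply(runs, `[[`, numeric(1), "shadow_max"))
  shmean_med <- stats::median(vapply(runs, `[[`, numeric(1), "shadow_mean"))

  tab <- data.frame(feature = feats,
                    confirmed_count_subsample = conf1,
                    confirmed_count_full = conf2,
                    stable = conf1 > R1 / 2 & conf2 > R2 / 2,
                    medianImp = med_imp,
                    ratio_to_shadow_max = med_imp / shmax_med,
                    ratio_to_shadow_mean = med_imp / shmean_med,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$medianImp, tab$feature, na.last = TRUE), ]
  tab$rank <- ifelse(is.na(tab$medianImp), NA_integer_, seq_len(nrow(tab)))
  rownames(tab) <- NULL
  structure(list(table = tab, R1 = R1, R2 = R2,
                 shadow_max_median = shmax_med,
                 shadow_mean_median = shmean_med,
                 subsample_fraction = subsample_fraction,
                 base_seed = base_seed),
            class = "lipid_stability")
}

#' @export
print.lipid_stability <- function(x, ...) {
  st <- x$table[x$table$stable, ]
  cat(sprintf("<lipid_stability> R1=%d subsample + R2=%d full runs; %d stable feature(s)\n",
              x$R1, x$R2, nrow(st)))
  if (nrow(st)) print(st[, c("feature", "confirmed_count_subsample",
                             "confirmed_count_full", "medianImp",
                             "ratio_to_shadow_max", "ratio_to_shadow_mean")],
                      digits = 3)
  invisible(x)
}

#' Shadow signal-to-noise ratios for stable features
#'
#' @param result A `lipid_stability` from [stability_protocol()].
#' @return Data frame of stable features with `medianImp`,
#'   `ratio_to_shadow_max` and `ratio_to_shadow_mean`.
#' @export
shadow_ratios <- function(result) {
  stopifnot(inherits(result, "lipid_stability"))
  st <- result$table[result$table$stable, , drop = FALSE]
  if (nrow(st) == 0L) stop("no stable features", call. = FALSE)
  if (result$shadow_max_median == 0 || result$shadow_mean_median == 0)
    stop("undefined ratio: zero shadow statistics", call. = FALSE)
  st[, c("feature", "medianImp", "ratio_to_shadow_max",
         "ratio_to_shadow_mean", "rank")]
}
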