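#' Log-transform an abundance matrix
#'
#' Applies `log2(x + delta)` per species, with `delta` equal to half the
#' smallest positive value of that species when zeros are present and 0
#' otherwise. Species that are zero in every sample are dropped with a
#' warning.
#'
#' @param abundance Non-negative numeric matrix, samples x species.
#' @return A list with `log2` (transformed matrix), `delta` (named vector of
#'   pseudocounts used) and `dropped` (names of all-zero species).
#' @export
preprocess_abundance <- function(abundance) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  if (any(abundance < 0)) stop("abundance values must be non-negative", call. = FALSE)
  all_zero <- colSums(abundance > 0) == 0L
  dropped <- colnames(abundance)[all_zero]
  if (length(dropped)) {
    warning("dropping all-zero species: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    abundance <- abundance[, !all_zero, drop = FALSE]
  }
  delta <- apply(abundance, 2, function(v) {
    if (any(v == 0)) min(v[v > 0]) / 2 else 0
  })
  log2m <- log2(sweep(abundance, 2, delta, "+"))
  list(log2 = log2m, delta = delta, dropped = dropped)
}

#' Two-sided Wilcoxon-Mann-Whitney p-value
#'
#' Uses the exact null distribution when the combined sample size is at most
#' 16 and there are no ties, and the normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param case_values,control_values Numeric vectors, each with at least 2
#'   finite values.
#' @return The two-sided p-value.
#' @examples
#' wilcoxon_mw(c(1, 2, 3), c(4, 5, 6)) # 0.1
#' @export
wilcoxon_mw <- function(case_values, control_values) {
  case_values <- case_values[is.finite(case_values)]
  control_values <- control_values[is.finite(control_values)]
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("insufficient data: each group needs at least 2 finite values", call. = FALSE)
  pooled <- c(case_values, control_values)
  exact <- (length(pooled) <= 16L) && !anyDuplicated(pooled)
  suppressWarnings(
    stats::wilcox.test(case_values, control_values, exact = exact,
                       correct = TRUE, alternative = "two.sided")$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1). Adjustment families are
#' per stratification level: species form one family, each stratum level its
#' own.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pseudo fold change between group medians
#'
#' `pseudo_fc = (median_case + eps) / (median_control + eps)` where `eps` is 0
#' when both medians are positive and otherwise half the smallest positive
#' pooled value; `log2fc = log2(pseudo_fc)`, positive when abundance is higher
#' in cases.
#'
#' @param case_values,control_values Non-negative numeric vectors.
#' @return A list with `median_case`, `median_control`, `epsilon`,
#'   `pseudo_fc`, `log2fc`.
#' @export
pseudo_fold_change <- function(case_values, control_values) {
  stopifnot(all(case_values >= 0), all(control_values >= 0))
  m1 <- stats::median(case_values)
  m0 <- stats::median(control_values)
  eps <- 0
  if (m1 == 0 || m0 == 0) {
    pos <- c(case_values, control_values)
    pos <- pos[pos > 0]
    if (length(pos) == 0L)
      stop("fold change undefined: both medians zero and no positive values",
           call. = FALSE)
    eps <- min(pos) / 2
  }
  fc <- (m1 + eps) / (m0 + eps)
  list(median_case = m1, median_control = m0, epsilon = eps,
       pseudo_fc = fc, log2fc = log2(fc))
}

#' Differential abundance at a stratification level
#'
#' At `level = "species"` each panel species is tested on its own; at any
#' other level the per-sample stratum value is the *sum* of that sample's
#' concentrations over member species (mass-preserving aggregation), and one
#' record is produced per stratum. Wilcoxon-Mann-Whitney p-values are
#' BH-adjusted within the level, and a feature is flagged significant when
#' `adj_p < alpha` and the fold-change magnitude `max(fc, 1/fc)` strictly
#' exceeds `fc_threshold`.
#'
#' @param cohort A `lipid_cohort` (or any list with `abundance` matrix and
#'   `group` factor with levels case/control).
#' @param annotation Annotation table from [annotate_lipids()] covering every
#'   abundance column; not needed for `level = "species"`.
#' @param level One of `"species"`, `"class"`, `"category"`, `"subcategory"`,
#'   `"subclass"`, `"total_fa"`, `"total_c"`, `"total_oh"`, `"ether_bond"`,
#'   `"saturation"`, `"bilayer_thickness"`, `"lateral_diffusion"`,
#'   `"intrinsic_curvature"`, `"function"`, `"cellular_component"`.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param fc_threshold Fold-change magnitude threshold (default 1: excludes
#'   only exact ties).
#' @return A data frame with one row per feature/stratum: `feature_id`,
#'   `level`, `n_species`, `median_case`, `median_control`, `pseudo_fc`,
#'   `log2fc`, `p_value`, `adj_p`, `significant`, ordered by `log2fc`.
#' @examples
#' co <- simulate_cohort(cohort_design(seed = 3), cll_effects())
#' de <- de_by_level(co, level = "species")
#' head(de[de$significant, ])
#' @export
de_by_level <- function(cohort, annotation = NULL, level = "species",
                        alpha = 0.05, fc_threshold = 1) {
  levels_ok <- c("species", "class", "category", "subcategory", "subclass",
                 "total_fa", "total_c", "total_oh", "ether_bond", "saturation",
                 "bilayer_thickness", "lateral_diffusion",
                 "intrinsic_curvature", "function", "cellular_component")
  if (!level %in% levels_ok)
    stop("unknown level '", level, "'; valid levels: ",
         paste(levels_ok, collapse = ", "), call. = FALSE)
  ab <- cohort$abundance
  grp <- cohort$group
  stopifnot(is.matrix(ab), all(levels(grp) == c("case", "control")))

  if (level == "species") {
    strata <- stats::setNames(as.list(colnames(ab)), colnames(ab))
  } else {
    if (is.null(annotation)) annotation <- annotate_lipids(colnames(ab))
    col <- switch(level,
      class = "lipid_class", category = "category", subcategory = "subcategory",
      subclass = "subclass", total_fa = "total_fa_label", total_c = "total_c",
      total_oh = "total_oh", ether_bond = "ether_bond",
      saturation = "saturation_class", "function" = "fn", level)
    if (!col %in% names(annotation))
      stop("annotation table lacks column '", col, "'", call. = FALSE)
    key <- annotation[[col]][match(colnames(ab), annotation$raw_name)]
    if (anyNA(key))
      stop("annotation does not cover every species at level '", level, "'",
           call. = FALSE)
    strata <- split(colnames(ab), as.character(key))
  }

  rows <- lapply(names(strata), function(st) {
    v <- rowSums(ab[, strata[[st]], drop = FALSE])
    fc <- pseudo_fold_change(v[grp == "case"], v[grp == "control"])
    p <- wilcoxon_mw(v[grp == "case"], v[grp == "control"])
    data.frame(feature_id = st, level = level,
               n_species = length(strata[[st]]),
               median_case = fc$median_case, median_control = fc$median_control,
               pseudo_fc = fc$pseudo_fc, log2fc = fc$log2fc,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  fc_mag <- pmax(out$pseudo_fc, 1 / out$pseudo_fc)
  out$significant <- out$adj_p < alpha & fc_mag > fc_threshold
  out <- out[order(out$log2fc), ]
  rownames(out) <- NULL
  out
}

#' Principal component analysis of log abundances
#'
#' PCA on feature-standardized (zero-mean, unit-variance) log2 abundances.
#' Constant features are dropped with a warning before standardization.
#'
#' @param log2m Samples x species matrix of log2 abundances (e.g.
#'   `preprocess_abundance(co$abundance)$log2`).
#' @param n_components Number of components to return (default
#'   `min(dim) - 1`, capped by the data rank).
#' @return A list of class `lipid_pca`: `scores` (samples x components),
#'   `loadings` (species x components), `explained_fraction`.
#' @export
pca_lipids <- function(log2m, n_components = NULL) {
  stopifnot(is.matrix(log2m), nrow(log2m) >= 2, ncol(log2m) >= 2)
  sds <- apply(log2m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant features: ",
            paste(colnames(log2m)[sds == 0], collapse = ", "), call. = FALSE)
    log2m <- log2m[, sds > 0, drop = FALSE]
  }
  pr <- stats::prcomp(log2m, center = TRUE, scale. = TRUE)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  k <- if (is.null(n_components)) length(pr$sdev) else min(n_components, length(pr$sdev))
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 explained_fraction = expl[seq_len(k)]),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat(sprintf("<lipid_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained_fraction[1],
              100 * x$explained_fraction[2]))
  invisible(x)
}

#' Unsupervised hierarchical clustering of samples and species
#'
#' Agglomerative clustering of z-scored (per species) log2 abundances,
#' Euclidean distance, complete linkage by default (configurable), applied to
#' both samples and species.
#'
#' @param log2m Samples x species log2 matrix.
#' @param method Linkage method passed to [stats::hclust()].
#' @return A list with `sample_tree`, `species_tree` (hclust objects) and
#'   `sample_order`, `species_order` (leaf orders).
#' @export
hier_cluster <- function(log2m, method = "complete") {
  stopifnot(is.matrix(log2m), nrow(log2m) >= 2)
  z <- scale(log2m)
  z[, attr(z, "scaled:scale") == 0] <- 0
  ts <- stats::hclust(stats::dist(z), method = method)
  tf <- stats::hclust(stats::dist(t(z)), method = method)
  list(sample_tree = ts, species_tree = tf,
       sample_order = rownames(log2m)[ts$order],
       species_order = colnames(log2m)[tf$order])
}
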