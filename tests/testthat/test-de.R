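test_that("log transform applies per-species pseudocounts only where zeros occur", {
  m <- cbind(a = c(1, 2, 4), b = c(0, 2, 4), c = c(0, 0, 0))
  expect_warning(p <- preprocess_abundance(m), "all-zero")
  expect_equal(p$dropped, "c")
  expect_equal(unname(p$delta), c(0, 1))
  expect_equal(unname(p$log2[, "a"]), log2(c(1, 2, 4)))
  expect_equal(unname(p$log2[, "b"]), log2(c(0, 2, 4) + 1))
  # all-positive table: plain log2
  q <- preprocess_abundance(m[, "a", drop = FALSE])
  expect_equal(unname(q$delta), 0)
})

test_that("Wilcoxon-Mann-Whitney matches enumeration on small samples", {
  expect_equal(wilcoxon_mw(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_mw(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_mw(1, c(1, 2)), "insufficient")
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxon_mw(x, y), bf_wilcoxon_perm(x, y), info = i)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bf_bh(p), info = i)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("pseudo fold change stabilizes zeros and is antisymmetric", {
  x <- c(3, 4, 5); y <- c(0.5, 1, 2)  # medians 4 and 1, all positive
  fc <- pseudo_fold_change(x, y)
  expect_equal(fc$pseudo_fc, 4)
  expect_equal(fc$log2fc, 2)
  expect_equal(fc$epsilon, 0)
  expect_equal(pseudo_fold_change(x, x)$log2fc, 0)
  expect_equal(pseudo_fold_change(y, x)$log2fc, -fc$log2fc)
  # zero median triggers the global-minimum pseudocount
  z <- pseudo_fold_change(c(0, 0, 4), c(1, 2, 3))
  expect_equal(z$epsilon, 0.5)
  expect_equal(z$pseudo_fc, 0.5 / 2.5)
  expect_error(pseudo_fold_change(c(0, 0), c(0, 0)), "undefined")
})

test_that("species-level DE recovers the implanted acylcarnitine signal", {
  for (s in 1:5) {
    co <- simulate_cohort(cohort_design(seed = 100 + s), cll_effects())
    de <- de_by_level(co, level = "species")
    row <- de[de$feature_id == "CAR 12:0", ]
    expect_true(row$significant, info = s)
    expect_gt(row$log2fc, 0)
    expect_true(all(de$adj_p >= de$p_value))
  }
})

test_that("group-swap antisymmetry: log2fc negates, p unchanged", {
  co <- simulate_cohort(cohort_design(seed = 21), cll_effects())
  sw <- co
  sw$group <- factor(ifelse(co$group == "case", "control", "case"),
                     levels = c("case", "control"))
  de1 <- de_by_level(co, level = "species")
  de2 <- de_by_level(sw, level = "species")
  de2 <- de2[match(de1$feature_id, de2$feature_id), ]
  expect_equal(de2$log2fc, -de1$log2fc, tolerance = 1e-12)
  expect_equal(de2$p_value, de1$p_value, tolerance = 1e-12)
})

test_that("null data gives calibrated raw p-values at the species level", {
  hits <- 0L; total <- 0L
  for (s in 1:50) {
    co <- simulate_cohort(cohort_design(seed = 3000 + s), effect_spec())
    de <- de_by_level(co, level = "species")
    hits <- hits + sum(de$p_value < 0.05)
    total <- total + nrow(de)
  }
  bounds <- qbinom(c(0.005, 0.995), total, 0.05) / total
  expect_gte(hits / total, bounds[1])
  expect_lte(hits / total, bounds[2])
})

test_that("class-level aggregation controls false positives under the null", {
  n_sig <- vapply(1:200, function(s) {
    co <- simulate_cohort(cohort_design(seed = 5000 + s), effect_spec())
    sum(de_by_level(co, level = "class")$significant)
  }, integer(1))
  expect_gte(mean(n_sig == 0L), 0.90)
})

test_that("strata aggregate by per-sample sums and single-member strata equal their species", {
  co <- simulate_cohort(cohort_design(seed = 8), cll_effects())
  an <- annotate_lipids(colnames(co$abundance))
  # the class partition covers each species exactly once: stratum sums conserve mass
  cls <- split(an$raw_name, an$lipid_class)
  expect_setequal(unlist(cls), colnames(co$abundance))
  strata_total <- Reduce(`+`, lapply(cls, function(sp)
    rowSums(co$abundance[, sp, drop = FALSE])))
  expect_equal(strata_total, rowSums(co$abundance), tolerance = 1e-9)
  # a stratum with one member reproduces the species-level test exactly
  de_cls <- de_by_level(co, an, level = "total_fa")
  single <- an$total_fa_label[!an$total_fa_label %in%
                                an$total_fa_label[duplicated(an$total_fa_label)]]
  de_sp <- de_by_level(co, level = "species")
  for (lab in single[1:3]) {
    sp <- an$raw_name[an$total_fa_label == lab]
    expect_equal(de_cls$p_value[de_cls$feature_id == lab],
                 de_sp$p_value[de_sp$feature_id == sp], info = lab)
  }
  expect_error(de_by_level(co, an, level = "flavor"), "valid levels")
})

test_that("PCA matches the closed-form eigendecomposition and orders variance", {
  # rank-1 data: one species varies, the rest are constant plus that signal
  set.seed(2)
  v <- rnorm(20)
  m <- cbind(a = v, b = 2 * v, c = -v)
  pc <- pca_lipids(m)
  expect_equal(pc$explained_fraction[1], 1, tolerance = 1e-10)

  x <- MASS::mvrnorm(200, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  colnames(x) <- c("a", "b")
  pc <- pca_lipids(x)
  ev <- eigen(cor(x))$values
  expect_equal(unname(pc$explained_fraction), ev / sum(ev), tolerance = 1e-10)
  co <- simulate_cohort(cohort_design(seed = 13), cll_effects())
  pc <- pca_lipids(preprocess_abundance(co$abundance)$log2)
  expect_true(all(diff(pc$explained_fraction) <= 1e-12))
  expect_true(all(pc$explained_fraction >= 0 & pc$explained_fraction <= 1))

  m2 <- cbind(a = v, const = rep(1, 20))
  expect_warning(pca_lipids(m2), "constant")
})

test_that("hierarchical clustering separates well-shifted groups into blocks", {
  expect_true({
    m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
    colnames(m) <- paste0("s", 1:3)
    hc <- hier_cluster(m)
    hc$sample_tree$height[1] < 1e-12
  })
  for (s in 1:3) {
    small <- default_panel()[1:12]
    co <- simulate_cohort(
      cohort_design(seed = 40 + s, panel = small),
      effect_spec(shifts = setNames(rep(3, 10), small[1:10]),
                  noise_sigma = 0.3))
    hc <- hier_cluster(preprocess_abundance(co$abundance)$log2)
    grp <- co$group[match(hc$sample_order, co$sample_id)]
    expect_equal(sum(diff(as.integer(grp)) != 0), 1L, info = s)
  }
  # permutation equivariance: same topology after row shuffling
  co <- simulate_cohort(cohort_design(seed = 44), cll_effects())
  l2 <- preprocess_abundance(co$abundance)$log2
  perm <- sample(nrow(l2))
  h1 <- hier_cluster(l2); h2 <- hier_cluster(l2[perm, ])
  expect_equal(sort(h1$sample_tree$height), sort(h2$sample_tree$height),
               tolerance = 1e-9)
  d1 <- cophenetic(h1$sample_tree); d2 <- cophenetic(h2$sample_tree)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)[rownames(m1), colnames(m1)]
  expect_equal(m1, m2, tolerance = 1e-9)
})
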