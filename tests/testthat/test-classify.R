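test_that("separable classes are fit perfectly and components are capped", {
  sep <- separable_matrix()
  fit <- reims_pcalda(sep$x, sep$labels)
  pred <- predict(fit, sep$x)
  expect_equal(pred$label, sep$labels)
  expect_lte(ncol(fit$pca_loadings), min(25, ncol(sep$x)))
  fit10 <- reims_pcalda(sep$x[, 1:10], sep$labels)
  expect_lte(ncol(fit10$pca_loadings), 10)
  expect_equal(ncol(fit$lda_directions), 1L)   # n_classes - 1
  expect_error(reims_pcalda(sep$x, rep("a", nrow(sep$x))), "2 classes")
  expect_error(reims_pcalda(sep$x, c("b", sep$labels[-1])), "fewer than 2")
})

test_that("fitting is invariant to sample order", {
  sep <- separable_matrix(n_per_class = 15, n_features = 8)
  fit <- reims_pcalda(sep$x, sep$labels)
  set.seed(6)
  perm <- sample.int(nrow(sep$x))
  fit_p <- reims_pcalda(sep$x[perm, ], sep$labels[perm])
  expect_equal(fit$feature_mean, fit_p$feature_mean)
  expect_equal(abs(fit$pca_loadings), abs(fit_p$pca_loadings),
               tolerance = 1e-8)
  probe <- matrix(stats::rnorm(5 * 8), 5)
  expect_equal(predict(fit, probe)$label, predict(fit_p, probe)$label)
})

test_that("distances, outlier rule and tie-breaks follow the contract", {
  sep <- separable_matrix(n_per_class = 30, n_features = 6, gap = 10)
  fit <- reims_pcalda(sep$x, sep$labels)
  # a synthetic spectrum placed exactly at a class centroid in feature
  # space projects to (near) zero distance and is no outlier
  cn <- colMeans(sep$x[sep$labels == "tumor", ])
  p <- predict(fit, cn)
  expect_equal(p$label, "tumor")
  expect_false(p$outlier)
  # walk >5 within-class SDs beyond both centroids along the
  # discriminant (unit pooled within-class variance): outlier flag
  dir_feat <- drop(fit$pca_loadings %*% fit$lda_directions)
  hi <- max(fit$class_centroids[, 1])
  v_far <- fit$feature_mean + ((hi + 6) / drop(crossprod(dir_feat))) *
    dir_feat
  p_far <- predict(fit, v_far)
  expect_true(p_far$outlier)
  expect_true(min(p_far$dist_tumor, p_far$dist_normal) > 5)
  # an exactly equidistant probe ties deterministically to the
  # lexicographically first label (symmetrized centroids, probe at the
  # feature mean so its discriminant score is exactly zero)
  fit_sym <- fit
  fit_sym$class_centroids[, 1] <- c(-1, 1)
  p_mid <- predict(fit_sym, fit_sym$feature_mean)
  expect_true(p_mid$tie)
  expect_equal(p_mid$label, "normal")
  expect_error(predict(fit, matrix(0, 1, 3)), "dimension")
})

test_that("predictions agree with an independent LDA oracle", {
  skip_if_not_installed("MASS")
  set.seed(123)
  for (rep in 1:5) {
    n <- 40; p <- sample(4:18, 1)
    x <- matrix(stats::rnorm(n * p), n)
    labels <- rep(c("A", "B"), each = n / 2)
    x[labels == "B", 1:2] <- x[labels == "B", 1:2] + 2.5
    fit <- reims_pcalda(x, labels, max_pca = p)   # full-rank PCA
    probe <- matrix(stats::rnorm(30 * p), 30)
    mine <- predict(fit, probe)$label
    oracle <- as.character(stats::predict(
      MASS::lda(x, grouping = labels), probe)$class)
    expect_equal(mine, oracle)
  }
})

test_that("near-zero variance features do not perturb predictions", {
  sep <- separable_matrix(n_per_class = 20, n_features = 5, gap = 8)
  fit <- reims_pcalda(sep$x, sep$labels, max_pca = 5)
  set.seed(8)
  pad <- matrix(stats::rnorm(nrow(sep$x) * 3, 0, 1e-9), nrow(sep$x))
  fit_pad <- reims_pcalda(cbind(sep$x, pad), sep$labels, max_pca = 5)
  probe <- matrix(stats::rnorm(10 * 5), 10)
  expect_equal(predict(fit, probe)$label,
               predict(fit_pad, cbind(probe, matrix(0, 10, 3)))$label)
})

test_that("cross-validation folds never leak the held-out unit", {
  prep <- default_cohort_prep()
  cv <- cross_validate(prep$x, prep$meta$tissue_label, prep$meta$site_id,
                       prep$meta$patient_id, "leave_patient_out")
  expect_equal(length(cv$folds), length(unique(prep$meta$patient_id)))
  for (f in cv$folds) {
    expect_length(intersect(f$train_units, f$test_units), 0)
  }
  cv_s <- cross_validate(prep$x, prep$meta$tissue_label, prep$meta$site_id,
                         prep$meta$patient_id, "leave_site_out")
  expect_equal(length(cv_s$folds), 3L)
  # pooled counts equal the sum of fold counts
  expect_equal(cv_s$pooled$counts,
               Reduce(`+`, lapply(cv_s$folds, function(f)
                 f$confusion$counts)))
  expect_equal(sum(cv_s$pooled$counts), nrow(prep$x))
})

test_that("strongly separated cohorts cross-validate above 95 percent", {
  prep <- default_cohort_prep()
  cv <- cross_validate(prep$x, prep$meta$tissue_label, prep$meta$site_id,
                       prep$meta$patient_id, "leave_site_out")
  expect_gte(cv$rates["ccr"], 95)
  # brute-force nearest-centroid oracle on the same data (leave-site-out)
  site <- prep$meta$site_id
  lab <- prep$meta$tissue_label
  correct <- 0
  for (s in unique(site)) {
    tr <- site != s
    mu_t <- colMeans(prep$x[tr & lab == "tumor", ])
    mu_n <- colMeans(prep$x[tr & lab == "normal", ])
    for (i in which(!tr)) {
      d_t <- sum((prep$x[i, ] - mu_t)^2)
      d_n <- sum((prep$x[i, ] - mu_n)^2)
      correct <- correct + ((d_t < d_n) == (lab[i] == "tumor"))
    }
  }
  expect_gte(100 * correct / nrow(prep$x), 95)
})

test_that("confusion metrics reproduce the published worked rates", {
  lopo <- matrix(c(69, 2, 1, 138), 2, byrow = TRUE,
                 dimnames = list(c("tumor", "normal"),
                                 c("tumor", "normal")))
  r <- confusion_metrics(lopo)
  expect_equal(round(r[["ccr"]], 2), 98.57)
  expect_equal(round(r[["fn_rate"]], 1), 2.8)
  expect_equal(round(r[["fp_rate"]], 2), 0.72)
  loso <- matrix(c(70, 1, 7, 132), 2, byrow = TRUE,
                 dimnames = list(c("tumor", "normal"),
                                 c("tumor", "normal")))
  r2 <- confusion_metrics(loso)
  expect_equal(round(r2[["fn_rate"]], 1), 1.4)
  expect_equal(round(r2[["fp_rate"]], 1), 5.0)
  perfect <- matrix(c(10, 0, 0, 20), 2, byrow = TRUE,
                    dimnames = list(c("tumor", "normal"),
                                    c("tumor", "normal")))
  expect_equal(unname(confusion_metrics(perfect)), c(100, 0, 0))
  # two-class identity: errors = fn_count + fp_count
  r3 <- confusion_metrics(loso)
  total <- sum(loso)
  expect_equal(r3[["ccr"]] / 100 * total,
               total - loso["tumor", "normal"] - loso["normal", "tumor"])
})

test_that("outlier-excluded denominators are available for rates", {
  counts <- matrix(c(70, 1, 7, 132), 2, byrow = TRUE,
                   dimnames = list(c("tumor", "normal"),
                                   c("tumor", "normal")))
  outl <- matrix(c(0, 0, 2, 0), 2, byrow = TRUE,
                 dimnames = dimnames(counts))
  cm <- reims_confusion(counts, outl)
  expect_equal(round(confusion_metrics(cm)[["ccr"]], 2), 96.19)
  expect_equal(round(confusion_metrics(cm,
                                       exclude_outliers = TRUE)[["ccr"]], 2),
               97.12)
})
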