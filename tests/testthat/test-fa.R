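test_that("l1 selection recovers planted bins and respects the cost knob", {
  set.seed(60)
  n <- 100; p_noise <- 4000
  x <- matrix(stats::rexp(2 * n * p_noise, 1 / 1e-4), 2 * n)
  planted <- c(101, 902, 1803, 2704, 3605)
  labels <- rep(c("normal", "tumor"), each = n)
  # informative but individually imperfect bins (overlapping exponentials)
  for (j in planted) {
    x[labels == "normal", j] <- stats::rexp(n, 1 / 2e-4)
    x[labels == "tumor", j] <- stats::rexp(n, 1 / 8e-4)
  }
  sel <- l1_feature_select(x, labels, cost = 500)
  expect_true(all(planted %in% sel$bin))
  expect_true(all(sel$enriched_in[match(planted, sel$bin)] == "tumor"))

  # exhaustive univariate AUC oracle ranks the same five bins on top
  auc <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    (sum(r[labels == "tumor"]) - n * (n + 1) / 2) / (n * n)
  }, numeric(1))
  expect_setequal(order(abs(auc - 0.5), decreasing = TRUE)[1:5], planted)

  # vanishing cost gives (near-)empty selection; size grows with cost
  expect_lte(nrow(l1_feature_select(x, labels, cost = 1e-6)), 1)
  sizes <- vapply(c(0.5, 50, 5000), function(cc)
    nrow(l1_feature_select(x, labels, cost = cc)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("shuffled labels select nothing systematically", {
  set.seed(61)
  n <- 50
  x <- matrix(stats::rexp(2 * n * 500, 1 / 1e-4), 2 * n)
  labels <- rep(c("normal", "tumor"), each = n)
  hits <- integer(20)
  for (i in 1:20) {
    sel <- l1_feature_select(x, sample(labels), cost = 500)
    hits[i] <- nrow(sel)
  }
  # no bin is informative, so selections stay sparse relative to p
  expect_lt(stats::median(hits), 60)
})

test_that("l1 sparsity keeps at most one of a duplicated column pair", {
  set.seed(62)
  n <- 40
  base <- c(stats::rnorm(n, 0), stats::rnorm(n, 3))
  labels <- rep(c("a", "b"), each = n)
  x <- cbind(base, base, matrix(stats::rnorm(2 * n * 5), 2 * n))
  colnames(x) <- NULL
  sel <- l1_feature_select(x, labels, cost = 10)
  expect_lte(sum(sel$bin %in% c(1, 2)), 1)
})

test_that("targeted models mirror the full-range contract", {
  sep <- separable_matrix(n_per_class = 25, n_features = 10, gap = 8)
  # one perfectly separating bin
  one <- targeted_model(sep$x, sep$labels, bins = 1:3)
  expect_equal(predict(one, sep$x[, 1:3])$label, sep$labels)
  expect_error(targeted_model(sep$x, sep$labels, bins = c(1, 99)),
               "outside")
  # pure-noise bins give near-chance accuracy
  set.seed(63)
  noise <- matrix(stats::rnorm(50 * 4), 50)
  fit_noise <- reims_pcalda(noise, sep$labels)
  acc <- mean(predict(fit_noise, noise)$label == sep$labels)
  expect_lt(acc, 0.85)
})

test_that("FA profile extraction reads the six channels by tolerance", {
  # only arachidonic acid present
  s <- reims_spectrum("s", 303.23, 100)
  p <- extract_fa_profile(s)
  expect_equal(as.numeric(p), c(0, 0, 0, 1, 0, 0))
  expect_true(attr(p, "valid"))
  # equal intensities in all six channels
  mzs <- sort(c(279.2329, 307.2643, 305.2486, 303.2329, 331.2643,
                329.2486))
  p6 <- extract_fa_profile(reims_spectrum("s", mzs, rep(50, 6)))
  expect_equal(as.numeric(p6), rep(1 / 6, 6))
  # a peak 0.12 Da off-reference needs the wider tolerance
  off <- reims_spectrum("s", 279.2329 + 0.12, 10)
  expect_false(attr(extract_fa_profile(off, tolerance = 0.05), "valid"))
  expect_true(attr(extract_fa_profile(off, tolerance = 0.2), "valid"))
  # no channel at all: flagged invalid
  none <- extract_fa_profile(reims_spectrum("s", 500, 10))
  expect_false(attr(none, "valid"))
})

test_that("omega-6 ratios follow their closed forms and are scale free", {
  prof <- stats::setNames(rep(1, 6), c("FA(18:2)", "FA(20:2)", "FA(20:3)",
                                       "FA(20:4)", "FA(22:4)", "FA(22:5)"))
  r <- fa_ratios(prof)
  expect_equal(unname(r[c("FA(22:4)/FA(20:4)", "FA(22:5)/FA(20:4)",
                          "FA(20:2)/FA(18:2)")]), c(1, 1, 1))
  expect_equal(unname(r[["products/FA(18:2)"]]), 5)
  prof2 <- stats::setNames(c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1), names(prof))
  expect_equal(unname(fa_ratios(prof2)[["products/FA(18:2)"]]), 1)
  # homogeneous of degree zero
  expect_equal(fa_ratios(prof2 * 37), fa_ratios(prof2))
  # zero denominators reported as NA with a reason
  prof0 <- stats::setNames(c(0, 1, 1, 0, 1, 1), names(prof))
  r0 <- fa_ratios(prof0)
  expect_true(all(is.na(r0)))
  expect_match(attr(r0, "undefined")[1], "zero denominator")
})

test_that("channel model fitting floors SDs and keeps its shape", {
  prof <- matrix(rep(c(0.4, 0.1, 0.1, 0.2, 0.1, 0.1), each = 6), 6,
                 dimnames = list(NULL, c("FA(18:2)", "FA(20:2)", "FA(20:3)",
                                         "FA(20:4)", "FA(22:4)",
                                         "FA(22:5)")))
  set.seed(64)
  prof2 <- prof + matrix(stats::runif(36, 0, 0.01), 6)
  fit <- channel_fit(rbind(prof, prof2), rep(c("WT", "Mut"), each = 6))
  expect_equal(dim(fit$location), c(2L, 6L))
  expect_equal(dim(fit$scale), c(2L, 6L))
  # degenerate class: medians equal the profile, SDs at the floor
  expect_equal(unname(fit$location["WT", ]), unname(prof[1, ]))
  expect_equal(unname(fit$scale["WT", ]),
               unname(pmax(1e-6 * prof[1, ], 1e-9)))
  expect_error(channel_fit(prof[1:2, ], c("WT", "WT")), "at least 3")
  # median robust to one extreme outlier
  v <- rbind(prof, prof)
  v[1, 1] <- 50
  fit_o <- channel_fit(v, rep("WT", 12))
  expect_equal(unname(fit_o$location["WT", 1]), 0.4)
})

test_that("channel classification equals the explicit density oracle", {
  set.seed(65)
  loc <- rbind(WT = c(0.40, 0.08, 0.10, 0.22, 0.10, 0.10),
               Mut = c(0.28, 0.12, 0.14, 0.22, 0.12, 0.12))
  sc <- rbind(WT = rep(0.05, 6), Mut = rep(0.07, 6))
  colnames(loc) <- colnames(sc) <- c("FA(18:2)", "FA(20:2)", "FA(20:3)",
                                     "FA(20:4)", "FA(22:4)", "FA(22:5)")
  model <- structure(list(location = loc, scale = sc,
                          class_labels = c("Mut", "WT"),
                          counts = c(10L, 10L)),
                     class = "reims_channel")
  probes <- matrix(stats::runif(1000 * 6, 0, 0.5), 1000,
                   dimnames = list(NULL, colnames(loc)))
  pred <- predict(model, probes)
  for (i in seq_len(1000)) {
    ll <- vapply(c("Mut", "WT"), function(cl) {
      tot <- 0
      for (j in 1:6) {                       # explicit Gaussian density
        tot <- tot - 0.5 * log(2 * pi) - log(sc[cl, j]) -
          (probes[i, j] - loc[cl, j])^2 / (2 * sc[cl, j]^2)
      }
      tot
    }, numeric(1))
    expect_equal(pred$label[i], names(ll)[which.max(ll)])
    expect_equal(pred$loglik_Mut[i], unname(ll["Mut"]), tolerance = 1e-9)
  }
  # profile at a class's medians with shared SDs classifies to it
  shared <- model; shared$scale[] <- 0.05
  expect_equal(predict(shared, loc["Mut", , drop = FALSE])$label, "Mut")
  # symmetric midpoint ties deterministically to the first class
  mid <- (loc["Mut", ] + loc["WT", ]) / 2
  p_mid <- predict(shared, matrix(mid, 1))
  expect_true(p_mid$tie)
  expect_equal(p_mid$label, "Mut")
})

test_that("equal-SD two-class channel model reduces to nearest median", {
  loc <- rbind(A = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
               B = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1))
  sc <- rbind(A = rep(0.1, 6), B = rep(0.1, 6))
  model <- structure(list(location = loc, scale = sc,
                          class_labels = c("A", "B"), counts = c(5L, 5L)),
                     class = "reims_channel")
  set.seed(66)
  probes <- matrix(stats::runif(200 * 6), 200)
  pred <- predict(model, probes)
  d_a <- rowSums(sweep(probes, 2, loc["A", ])^2)
  d_b <- rowSums(sweep(probes, 2, loc["B", ])^2)
  expect_equal(pred$label, ifelse(d_a <= d_b, "A", "B"))
})

test_that("channel cross-validation is stratified, seeded and calibrated", {
  set.seed(67)
  n <- 30
  wt <- matrix(stats::rnorm(n * 6, 0.5, 0.02), n)
  mut <- matrix(stats::rnorm(n * 6, 0.2, 0.02), n)
  prof <- rbind(wt, mut)
  labels <- rep(c("WT", "Mut"), each = n)
  cv <- channel_crossval(prof, labels, folds = 5, seed = 2)
  expect_equal(cv$accuracy, 1.0)
  expect_equal(cv$sensitivity, 1.0)
  expect_equal(cv$specificity, 1.0)
  expect_identical(cv$fold_id,
                   channel_crossval(prof, labels, folds = 5,
                                    seed = 2)$fold_id)
  expect_true(all(table(cv$fold_id, labels) >= floor(n / 5)))
  expect_error(channel_crossval(prof[1:8, ], labels[c(1:4, 31:34)],
                                folds = 5), "at least as many")
  # permuted labels fall to (near) the majority-class prior
  perm_acc <- replicate(20, channel_crossval(
    prof, sample(labels), folds = 5, seed = 3)$accuracy)
  expect_lt(mean(perm_acc), 0.68)
})

test_that("channel CV accuracy rises with the planted FA effect size", {
  accs <- vapply(c(0, 0.5, 1), function(s) {
    cfg <- cohort_config(
      fa_effect_sizes = scale_fa_effects(default_fa_effects(), s),
      patients_per_site = 10, points_per_patient = 4, scans_per_point = 1,
      tumor_fraction = 1, tumor_pct_sampler = function(n) rep(90, n),
      pik3ca_mut_fraction = 0.5, seed = 68)
    sim <- simulate_cohort(cfg)
    prof <- t(vapply(sim$dataset$spectra,
                     function(x) as.numeric(extract_fa_profile(x)),
                     numeric(6)))
    colnames(prof) <- c("FA(18:2)", "FA(20:2)", "FA(20:3)", "FA(20:4)",
                        "FA(22:4)", "FA(22:5)")
    channel_crossval(prof, sim$dataset$meta$pik3ca_status, folds = 5,
                     seed = 69)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1] + 0.1)
  expect_gt(accs[3], 0.7)
})

test_that("planted mutant effects raise the omega-6 sum ratio", {
  cfg <- cohort_config(patients_per_site = 6, points_per_patient = 4,
                       scans_per_point = 1, tumor_fraction = 1,
                       tumor_pct_sampler = function(n) rep(90, n),
                       pik3ca_mut_fraction = 0.5, seed = 70)
  sim <- simulate_cohort(cfg)
  ratios <- vapply(sim$dataset$spectra, function(s)
    fa_ratios(extract_fa_profile(s))[["products/FA(18:2)"]], numeric(1))
  grp <- sim$dataset$meta$pik3ca_status
  expect_gt(stats::median(ratios[grp == "Mut"]),
            stats::median(ratios[grp == "WT"]))
})

test_that("Tukey box statistics follow the fence rule", {
  b <- tukey_box_stats(1:100)
  expect_equal(b$median, 50.5)
  expect_length(b$flagged, 0)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 100)
  b2 <- tukey_box_stats(c(1, 2, 3, 4, 100))
  expect_equal(b2$flagged, 100)
  expect_equal(b2$whisker_high, 4)
  b3 <- tukey_box_stats(rep(7, 6))
  expect_equal(c(b3$q1, b3$median, b3$q3), c(7, 7, 7))
  expect_equal(c(b3$whisker_low, b3$whisker_high), c(7, 7))
  expect_error(tukey_box_stats(1:3), "at least 4")
  # quartiles use linear interpolation (type 7)
  v <- c(2, 4, 6, 8, 10, 12, 14, 16)
  b4 <- tukey_box_stats(v)
  expect_equal(c(b4$q1, b4$q3),
               unname(stats::quantile(v, c(0.25, 0.75), type = 7)))
})
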