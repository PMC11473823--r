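# Small in-code fixtures shared across test files.

# Two-scan dataset with one annotated tumor point and one pure-normal
# point; intensities chosen so TICs straddle nothing in particular.
tiny_dataset <- function() {
  s1 <- reims_spectrum("sA", c(554.26, 699.50, 744.55, 885.55),
                       c(5e4, 3e5, 4e5, 2e5))
  s2 <- reims_spectrum("sB", c(554.26, 865.71, 893.74, 919.75),
                       c(5e4, 6e5, 7e5, 5e5))
  meta <- scan_metadata(c("sA", "sB"), site_id = c("C1", "C1"),
                        patient_id = c("P1", "P2"),
                        point_id = c("pt1", "pt2"),
                        cautery_mode = c("cut", "coag"),
                        tumor_cell_pct = c(80, 0),
                        adipose_pure = c(FALSE, TRUE),
                        pik3ca_status = c("Mut", "unknown"))
  reims_dataset(list(s1, s2), meta)
}

# Noise-free template with known peak means, for exact-arithmetic tests.
flat_template <- function(mz = c(700, 800, 900), mean = c(100, 300, 500),
                          cv = 0, noise = 0) {
  class_template("flat",
                 data.frame(mz = mz, mean_intensity = mean, cv = cv),
                 baseline_noise_level = noise, noise_peak_rate = 0,
                 lockmass_intensity = 0)
}

# Well-separated two-class feature matrix with block-diagonal means.
separable_matrix <- function(n_per_class = 20, n_features = 12, gap = 6,
                             sd = 1, seed = 99) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * n_features, 0, sd),
                    n_per_class),
             matrix(stats::rnorm(n_per_class * n_features, 0, sd),
                    n_per_class))
  x[(n_per_class + 1):(2 * n_per_class), 1:3] <-
    x[(n_per_class + 1):(2 * n_per_class), 1:3] + gap
  list(x = x, labels = rep(c("normal", "tumor"), each = n_per_class))
}

# Preprocessed default synthetic cohort, cached per session (built once,
# reused by classifier and acceptance tests).
default_cohort_prep <- local({
  cache <- NULL
  function(seed = 2024) {
    if (is.null(cache)) {
      sim <- simulate_cohort(cohort_config(seed = seed))
      prep <- preprocess_dataset(sim$dataset)
      keep <- prep$meta$tissue_label %in% c("tumor", "normal")
      cache <<- list(x = prep$x[keep, , drop = FALSE],
                     meta = prep$meta[keep, , drop = FALSE],
                     prep = prep, truth = sim$truth)
    }
    cache
  }
})
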