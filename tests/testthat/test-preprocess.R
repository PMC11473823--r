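test_that("background subtraction is clipped, monotone and flag-aware", {
  s <- reims_spectrum("s", c(700, 800), c(100, 300))
  expect_equal(subtract_background(s, 0)$intensity, c(100, 300))
  expect_equal(subtract_background(s, 50)$intensity, c(50, 250))
  z <- subtract_background(s, 300)
  expect_equal(z$intensity, c(0, 0))
  expect_true(isTRUE(attr(z, "all_zero")))
  expect_error(subtract_background(s, -1), "non-negative")
  expect_true(tic(subtract_background(s, 10)) <= tic(s))
})

test_that("lockmass correction lands the reference peak exactly", {
  cfg <- preprocess_config()
  s <- reims_spectrum("s", c(554.30, 700.04), c(5e4, 1e5))
  lc <- lockmass_correct(s, cfg)
  expect_equal(lc$shift, -0.0385)
  i <- which.min(abs(lc$spectrum$mz - 554.2615))
  expect_lt(abs(lc$spectrum$mz[i] - 554.2615), 1e-9)
  expect_equal(lc$spectrum$mz[2], 700.04 - 0.0385)

  s0 <- reims_spectrum("s", c(554.2615, 700), c(5e4, 1e5))
  lc0 <- lockmass_correct(s0, cfg)
  expect_equal(lc0$shift, 0)
  expect_equal(lc0$spectrum$mz, s0$mz)

  s_none <- reims_spectrum("s", c(600, 700), c(10, 10))
  lc_bad <- lockmass_correct(s_none, cfg)
  expect_true(is.na(lc_bad$shift))
  expect_true(isTRUE(attr(lc_bad$spectrum, "lockmass_failed")))
  expect_equal(lc_bad$spectrum$mz, s_none$mz)
})

test_that("the most intense in-window peak is the lockmass anchor", {
  cfg <- preprocess_config()
  s <- reims_spectrum("s", c(554.10, 554.31), c(9e4, 5e4))
  expect_equal(lockmass_correct(s, cfg)$shift, 554.2615 - 554.10)
})

test_that("binning follows the half-open 0.1 Da grid and conserves intensity", {
  cfg <- preprocess_config()
  s <- reims_spectrum("s", c(893.71, 893.74), c(10, 20))
  b <- bin_spectrum(s, cfg)
  expect_equal(sum(b$values > 0), 1L)
  expect_equal(unname(b$values[b$values > 0]), 30)
  expect_equal(names(b$values)[b$values > 0], "mz_893.75")

  edge <- bin_spectrum(reims_spectrum("s", c(599.99, 600.0, 999.99, 1000.0),
                                      c(1, 2, 3, 4)), cfg)
  expect_equal(sum(edge$values), 2 + 3)   # 599.99 and 1000.0 out of range
  expect_equal(unname(edge$values[1]), 2)

  # conservation against a brute-force per-peak assignment oracle
  set.seed(10)
  for (rep in 1:10) {
    mz <- sort(stats::runif(200, 550, 1050))
    ints <- stats::rexp(200, 1 / 100)
    s <- reims_spectrum("s", mz, ints)
    b <- bin_spectrum(s, cfg)
    oracle <- numeric(4000)
    for (k in seq_along(mz)) {
      if (mz[k] >= 600 && mz[k] < 1000) {
        j <- floor((mz[k] - 600) / 0.1) + 1
        oracle[j] <- oracle[j] + ints[k]
      }
    }
    expect_equal(unname(b$values), oracle)
    expect_equal(sum(b$values), sum(ints[mz >= 600 & mz < 1000]))
  }
})

test_that("TIC normalization is exact, idempotent and scale invariant", {
  cfg <- preprocess_config(grid_start = 600, grid_end = 600.3,
                           bin_width = 0.1)
  s <- reims_spectrum("s", c(600.05, 600.15, 600.25), c(2, 3, 5))
  n1 <- tic_normalize(bin_spectrum(s, cfg))
  expect_equal(unname(n1$values), c(0.2, 0.3, 0.5))
  expect_true(n1$normalized)
  expect_equal(tic_normalize(n1)$values, n1$values)
  s2 <- reims_spectrum("s", c(600.05, 600.15, 600.25), 7 * c(2, 3, 5))
  expect_equal(tic_normalize(bin_spectrum(s2, cfg))$values, n1$values)
  zero <- bin_spectrum(reims_spectrum("s", 500, 1), cfg)
  expect_error(tic_normalize(zero), "all-zero")
})

test_that("QC filter applies the strict 2e4 floor and lockmass flags", {
  mk <- function(id, total) reims_spectrum(id, c(554.26, 700),
                                           c(total * 0.1, total * 0.9))
  meta <- scan_metadata(c("a", "b", "c"), site_id = "C1",
                        patient_id = c("P1", "P2", "P3"), point_id = "pt1")
  d <- reims_dataset(list(mk("a", 1.9e4), mk("b", 2.1e4), mk("c", 2.0e4)),
                     meta)
  qc <- qc_filter(d)
  expect_equal(qc$kept$meta$scan_id, c("b", "c"))   # exactly 2e4 is kept
  expect_equal(qc$reasons$reason, "low_tic")
  # idempotent
  qc2 <- qc_filter(qc$kept)
  expect_equal(length(qc2$excluded), 0L)
  expect_equal(qc2$kept$meta, qc$kept$meta)
  # lockmass failures are excluded regardless of TIC
  bad <- mk("a", 1e6)
  attr(bad, "lockmass_failed") <- TRUE
  d2 <- reims_dataset(list(bad), scan_metadata("a", site_id = "C1",
                                               patient_id = "P1",
                                               point_id = "pt1"))
  expect_equal(qc_filter(d2)$reasons$reason, "lockmass_failed")
  # empty dataset passes through
  empty <- reims_dataset(list(), scan_metadata(character()))
  expect_equal(length(qc_filter(empty)$kept), 0L)
})

test_that("histology labels follow the 30% / pure-adipose rules per point", {
  mk <- function(id) reims_spectrum(id, 700, 10)
  meta <- scan_metadata(
    paste0("s", 1:5),
    site_id = "C1", patient_id = "P1",
    point_id = c("pt1", "pt2", "pt3", "pt4", "pt5"),
    tumor_cell_pct = c(30, 29, 0, 0, NA),
    adipose_pure = c(FALSE, FALSE, TRUE, FALSE, NA))
  d <- reims_dataset(lapply(paste0("s", 1:5), mk), meta)
  expect_warning(out <- assign_labels(d), "unassigned")
  expect_equal(out$meta$tissue_label,
               c("tumor", "excluded", "normal", "excluded", "unassigned"))
  # labels partition the points: one label per point, propagated to scans
  meta2 <- scan_metadata(c("a1", "a2"), site_id = "C1", patient_id = "P1",
                         point_id = "pt1", tumor_cell_pct = 45,
                         adipose_pure = FALSE)
  d2 <- reims_dataset(list(mk("a1"), mk("a2")), meta2)
  expect_equal(unique(assign_labels(d2)$meta$tissue_label), "tumor")
})

test_that("the preprocessing chain is deterministic end to end", {
  sim <- simulate_cohort(cohort_config(patients_per_site = 2,
                                       points_per_patient = 2,
                                       scans_per_point = 1, seed = 31))
  p1 <- preprocess_dataset(sim$dataset)
  p2 <- preprocess_dataset(sim$dataset)
  expect_identical(p1$x, p2$x)
  expect_true(all(abs(rowSums(p1$x) - 1) < 1e-9))
  # lockmass shifts undo the planted site drift
  drift <- vapply(default_sites(), `[[`, numeric(1), "mass_drift")
  names(drift) <- vapply(default_sites(), `[[`, character(1), "site_id")
  expect_equal(unname(p1$shifts), unname(-drift[sim$dataset$meta$site_id]),
               tolerance = 1e-9)
})
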