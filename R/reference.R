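#' Reference multi-centre cohort design (sampling-event counts)
#'
#' Per-patient counts of REIMS sampling events ("burns") in normal (N)
#' and tumor (T) tissue under cut (C) and coagulation (CG) cautery for
#' the three-centre breast study design this package emulates: 21
#' patients across centres C1, C3 and C4. Column sums give the cohort
#' totals (82 normal-cut, 57 normal-coag, 39 tumor-cut, 32 tumor-coag;
#' 139 normal and 71 tumor spectra in all) that the `"table1_like"`
#' simulation preset reproduces.
#'
#' @return data.frame with columns `center`, `patient`, `n_cut`,
#'   `n_coag`, `t_cut`, `t_coag`.
#' @export
cohort_reference <- function() {
  data.frame(
    center = rep(c("C1", "C3", "C4"), c(6, 8, 7)),
    patient = c(1:6, 1:8, 1:7),
    n_cut = c(5, 3, 5, 0, 4, 4,  5, 5, 5, 5, 5, 0, 0, 5,  8, 8, 9, 3, 0,
              0, 3),
    n_coag = c(4, 2, 5, 0, 5, 3,  1, 2, 4, 3, 3, 2, 0, 4,  6, 4, 5, 2, 0,
               0, 2),
    t_cut = c(4, 0, 0, 0, 0, 0,  5, 2, 1, 3, 5, 3, 3, 2,  2, 0, 0, 3, 3,
              3, 0),
    t_coag = c(2, 0, 0, 3, 4, 0,  3, 0, 0, 4, 5, 0, 3, 5,  2, 0, 0, 0, 1,
               0, 0)
  )
}

#' Reclassification-rate arithmetic for sub-threshold sampling points
#'
#' Sampling points with under-threshold tumor-cell content are excluded
#' from model building, then classified post hoc; this helper carries
#' out the bookkeeping relating the printed percentage to counts: the
#' implied number of correctly recognized points, and the rate after
#' removing outlier-flagged points from the denominator.
#'
#' @param n_points Number of excluded sampling points classified.
#' @param pct_correct Percentage reported correct (of all points).
#' @param n_outliers Outlier-flagged points removed for the adjusted
#'   rate.
#' @return List: `n_correct` (implied count), `pct_correct`
#'   (recomputed, percent), `pct_excl_outliers` (percent after outlier
#'   removal).
#' @examples
#' reclassification_rates(46, 67.4, 4)  # 31 correct; 73.8% of 42
#' @export
reclassification_rates <- function(n_points, pct_correct, n_outliers = 0) {
  stopifnot(n_points > 0, pct_correct >= 0, pct_correct <= 100,
            n_outliers >= 0, n_outliers < n_points)
  n_correct <- round(pct_correct / 100 * n_points)
  list(n_correct = n_correct,
       pct_correct = 100 * n_correct / n_points,
       pct_excl_outliers = 100 * n_correct / (n_points - n_outliers))
}
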