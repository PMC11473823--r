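#' Preprocessing parameters
#'
#' Defaults follow the standard REIMS workflow: lockmass reference at the
#' deprotonated leucine-enkephalin ion m/z 554.2615 with a +/- 0.5 Da
#' search window, 0.1 Da bins over m/z 600-1000 (the
#' phospholipid/triglyceride region), a raw-TIC quality floor of 2e4
#' counts (strictly below excludes) and a 30% tumor-cell labeling
#' threshold (at or above labels tumor).
#'
#' @param lockmass_reference,lockmass_tolerance Da.
#' @param bin_width,grid_start,grid_end Binning grid (Da).
#' @param min_scan_intensity Raw-TIC QC floor (counts).
#' @param tumor_label_threshold Percent tumor cells for a "tumor" label.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(lockmass_reference = 554.2615,
                              lockmass_tolerance = 0.5, bin_width = 0.1,
                              grid_start = 600, grid_end = 1000,
                              min_scan_intensity = 2e4,
                              tumor_label_threshold = 30) {
  stopifnot(grid_start < grid_end, bin_width > 0, lockmass_tolerance > 0,
            min_scan_intensity >= 0, tumor_label_threshold >= 0)
  structure(list(lockmass_reference = lockmass_reference,
                 lockmass_tolerance = lockmass_tolerance,
                 bin_width = bin_width, grid_start = grid_start,
                 grid_end = grid_end,
                 min_scan_intensity = min_scan_intensity,
                 tumor_label_threshold = tumor_label_threshold),
            class = "preprocess_config")
}

#' Background subtraction
#'
#' Subtracts a per-scan baseline from every peak, clipping at zero. With
#' `background = NULL` the baseline is estimated as the lower-quartile
#' peak intensity of the scan — a scalar chemical-noise level drawn from
#' the signal-free (low-intensity) portion of the peak list. A scalar or
#' per-peak numeric background may be supplied instead, e.g. from a
#' pre-burn solvent spectrum.
#'
#' @param spectrum A [reims_spectrum()].
#' @param background `NULL`, a non-negative scalar, or a per-peak vector.
#' @return The background-subtracted spectrum; all-zero results are
#'   flagged with `attr(, "all_zero")`.
#' @export
subtract_background <- function(spectrum, background = NULL) {
  stopifnot(inherits(spectrum, "reims_spectrum"))
  if (length(spectrum$intensity) == 0L) return(spectrum)
  if (is.null(background)) {
    background <- unname(stats::quantile(spectrum$intensity, 0.25, type = 7))
  }
  if (any(background < 0)) stop("background must be non-negative")
  if (!length(background) %in% c(1L, length(spectrum$intensity))) {
    stop("background must be scalar or one value per peak")
  }
  out <- spectrum
  out$intensity <- pmax(spectrum$intensity - background, 0)
  if (all(out$intensity == 0)) attr(out, "all_zero") <- TRUE
  out
}

#' Lockmass correction against the LeuEnk reference ion
#'
#' Locates the most intense peak within `lockmass_tolerance` of the
#' reference m/z and applies a uniform additive shift so that peak lands
#' exactly on the reference. If no peak lies in the window the spectrum is
#' passed through unshifted with `attr(, "lockmass_failed") = TRUE`
#' (such scans are excluded from modeling by [qc_filter()]).
#'
#' @param spectrum A [reims_spectrum()].
#' @param config A [preprocess_config()].
#' @return List with `spectrum` (corrected, `lockmass_shift` recorded) and
#'   `shift` (Da, `NA` on failure).
#' @export
lockmass_correct <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "reims_spectrum"))
  if (length(spectrum$mz) == 0L) stop("empty spectrum")
  ref <- config$lockmass_reference
  win <- which(abs(spectrum$mz - ref) <= config$lockmass_tolerance)
  if (length(win) == 0L) {
    out <- spectrum
    attr(out, "lockmass_failed") <- TRUE
    return(list(spectrum = out, shift = NA_real_))
  }
  peak <- win[which.max(spectrum$intensity[win])]
  shift <- ref - spectrum$mz[peak]
  out <- spectrum
  out$mz <- spectrum$mz + shift
  out$lockmass_shift <- shift
  list(spectrum = out, shift = shift)
}

#' Bin a scan onto the fixed m/z grid
#'
#' Bin `b` covers the half-open interval
#' `[grid_start + (b-1) w, grid_start + b w)`; peak intensities are summed
#' within bins and peaks outside `[grid_start, grid_end)` are discarded,
#' so total in-range intensity is conserved exactly.
#'
#' @param spectrum A (lockmass-corrected) [reims_spectrum()].
#' @param config A [preprocess_config()].
#' @return An object of class `binned_spectrum`: fields `grid_start`,
#'   `grid_end`, `bin_width`, `values`, `normalized`, plus bin-centre
#'   names on `values`.
#' @export
bin_spectrum <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "reims_spectrum"))
  n <- round((config$grid_end - config$grid_start) / config$bin_width)
  idx <- floor((spectrum$mz - config$grid_start) / config$bin_width) + 1
  keep <- idx >= 1 & idx <= n & spectrum$mz < config$grid_end &
    spectrum$mz >= config$grid_start
  values <- numeric(n)
  if (any(keep)) {
    s <- rowsum(spectrum$intensity[keep], group = idx[keep])
    values[as.integer(rownames(s))] <- s[, 1]
  }
  names(values) <- sprintf("mz_%.2f", config$grid_start +
                             (seq_len(n) - 0.5) * config$bin_width)
  structure(list(grid_start = config$grid_start,
                 grid_end = config$grid_end,
                 bin_width = config$bin_width, values = values,
                 normalized = FALSE, scan_id = spectrum$scan_id),
            class = "binned_spectrum")
}

#' Total-ion-count normalization
#'
#' Divides a binned spectrum by its bin sum so values sum to 1, making
#' profiles comparable across scans of different absolute intensity.
#' Idempotent; errors on an all-zero vector.
#'
#' @param binned A `binned_spectrum` from [bin_spectrum()].
#' @return The normalized `binned_spectrum`.
#' @export
tic_normalize <- function(binned) {
  stopifnot(inherits(binned, "binned_spectrum"))
  s <- sum(binned$values)
  if (s <= 0) stop("TIC normalization error: all-zero binned spectrum")
  binned$values <- binned$values / s
  binned$normalized <- TRUE
  binned
}

#' Quality-control scan filter
#'
#' Moves scans whose raw (pre-normalization, post background subtraction)
#' TIC is strictly below `min_scan_intensity`, and scans whose lockmass
#' correction failed, into the excluded set with machine-readable reason
#' codes (`"low_tic"`, `"lockmass_failed"`). Idempotent.
#'
#' @param dataset A [reims_dataset()] of raw spectra.
#' @param config A [preprocess_config()].
#' @param lockmass_failed Optional logical vector (one per scan) marking
#'   scans whose lockmass correction failed; defaults to the
#'   `lockmass_failed` attribute carried by each spectrum.
#' @return List with `kept` and `excluded` datasets and a data.frame
#'   `reasons` (`scan_id`, `reason`) for the excluded scans.
#' @export
qc_filter <- function(dataset, config = preprocess_config(),
                      lockmass_failed = NULL) {
  stopifnot(inherits(dataset, "reims_dataset"))
  n <- length(dataset$spectra)
  if (is.null(lockmass_failed)) {
    lockmass_failed <- vapply(dataset$spectra, function(s)
      isTRUE(attr(s, "lockmass_failed")), logical(1))
  }
  tics <- vapply(dataset$spectra, tic, numeric(1))
  low <- tics < config$min_scan_intensity
  reason <- ifelse(lockmass_failed, "lockmass_failed",
                   ifelse(low, "low_tic", NA_character_))
  bad <- !is.na(reason)
  list(kept = subset_scans(dataset, !bad),
       excluded = subset_scans(dataset, bad),
       reasons = data.frame(scan_id = dataset$meta$scan_id[bad],
                            reason = reason[bad],
                            stringsAsFactors = FALSE))
}

#' Histology-derived tissue label assignment
#'
#' Applies the labeling rule per sampling point and propagates the label
#' to all scans of the point: tumor-cell percentage at or above the
#' threshold labels `"tumor"`; exactly 0% with pure normal adipose
#' histology labels `"normal"`; anything in between — or a 0% point whose
#' surroundings are not 100% adipose — is `"excluded"`. Points without a
#' percentage annotation stay `"unassigned"` with a warning.
#'
#' @param dataset A [reims_dataset()] whose metadata carries
#'   `tumor_cell_pct` (and optionally `adipose_pure`) per sampling point.
#' @param config A [preprocess_config()].
#' @return The dataset with `tissue_label` filled in.
#' @export
assign_labels <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "reims_dataset"))
  m <- dataset$meta
  key <- paste(m$site_id, m$patient_id, m$point_id, sep = "\r")
  thr <- config$tumor_label_threshold
  for (k in unique(key)) {
    rows <- which(key == k)
    pct <- m$tumor_cell_pct[rows]
    pct <- pct[!is.na(pct)][1]
    pure <- m$adipose_pure[rows]
    pure <- pure[!is.na(pure)][1]
    label <- if (is.na(pct)) {
      warning("sampling point without tumor_cell_pct annotation: ",
              m$point_id[rows[1]], " left unassigned")
      "unassigned"
    } else if (pct >= thr) {
      "tumor"
    } else if (pct == 0 && !isFALSE(pure)) {
      "normal"
    } else {
      "excluded"
    }
    m$tissue_label[rows] <- label
  }
  dataset$meta <- m
  dataset
}

#' Run the full preprocessing chain over a dataset
#'
#' Background subtraction, lockmass correction, QC filtering (raw-TIC
#' floor and lockmass failures), binning, TIC normalization and label
#' assignment, in that order. Returns the scan-by-bin intensity matrix
#' the classifiers consume.
#'
#' @param dataset A [reims_dataset()] of raw spectra.
#' @param config A [preprocess_config()].
#' @param subtract Logical; apply background subtraction (default TRUE).
#' @return List: `x` (matrix, scans x bins, TIC-normalized), `meta`
#'   (metadata for kept scans, labels assigned), `bin_centers`, `kept`
#'   (the corrected, QC-passing dataset with labels), `excluded`
#'   (dataset), `reasons`, `shifts` (applied lockmass shifts).
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config(),
                               subtract = TRUE) {
  stopifnot(inherits(dataset, "reims_dataset"))
  spectra <- dataset$spectra
  shifts <- rep(NA_real_, length(spectra))
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]
    if (subtract) s <- subtract_background(s)
    lc <- lockmass_correct(s, config)
    spectra[[k]] <- lc$spectrum
    shifts[k] <- lc$shift
  }
  work <- reims_dataset(unname(spectra), dataset$meta, dataset$provenance)
  qc <- qc_filter(work, config)
  kept <- assign_labels(qc$kept, config)
  n <- round((config$grid_end - config$grid_start) / config$bin_width)
  centers <- config$grid_start + (seq_len(n) - 0.5) * config$bin_width
  x <- matrix(0, nrow = length(kept$spectra), ncol = n,
              dimnames = list(kept$meta$scan_id,
                              sprintf("mz_%.2f", centers)))
  for (k in seq_along(kept$spectra)) {
    b <- bin_spectrum(kept$spectra[[k]], config)
    if (sum(b$values) > 0) b <- tic_normalize(b)
    x[k, ] <- b$values
  }
  list(x = x, meta = kept$meta, bin_centers = centers, kept = kept,
       excluded = qc$excluded, reasons = qc$reasons,
       shifts = stats::setNames(shifts, dataset$meta$scan_id))
}
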