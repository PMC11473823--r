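#' Construct a single REIMS scan
#'
#' A `reims_spectrum` is one 1-second scan as a centroided peak list:
#' a strictly ascending vector of m/z values with matching non-negative
#' intensities, plus the lockmass shift if one has been applied.
#'
#' @param scan_id Character scalar identifying the scan.
#' @param mz Numeric vector of m/z values (Da), strictly ascending.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param lockmass_shift Signed additive m/z shift (Da) already applied to
#'   this scan, or `NA` if none.
#' @return An object of class `reims_spectrum`.
#' @examples
#' s <- reims_spectrum("scan1", c(554.26, 744.55, 893.74), c(5e4, 2e5, 8e5))
#' tic(s)
#' @export
reims_spectrum <- function(scan_id, mz, intensity, lockmass_shift = NA_real_) {
  stopifnot(is.character(scan_id), length(scan_id) == 1L)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have equal length (scan ", scan_id, ")")
  }
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("m/z values must be strictly ascending (scan ", scan_id, ")")
  }
  if (any(intensity < 0)) {
    stop("intensities must be non-negative (scan ", scan_id, ")")
  }
  structure(
    list(scan_id = scan_id, mz = mz, intensity = intensity,
         lockmass_shift = as.numeric(lockmass_shift)),
    class = "reims_spectrum"
  )
}

#' @export
print.reims_spectrum <- function(x, ...) {
  cat("<reims_spectrum> scan", x$scan_id, "-", length(x$mz), "peaks")
  if (length(x$mz)) {
    cat(sprintf(", m/z %.4f-%.4f, TIC %.3g", min(x$mz), max(x$mz),
                sum(x$intensity)))
  }
  if (!is.na(x$lockmass_shift)) {
    cat(sprintf(", lockmass shift %+.4f Da", x$lockmass_shift))
  }
  cat("\n")
  invisible(x)
}

#' Total ion count of a scan
#'
#' @param x A `reims_spectrum`.
#' @return Sum of all peak intensities.
#' @export
tic <- function(x) {
  stopifnot(inherits(x, "reims_spectrum"))
  sum(x$intensity)
}

metadata_columns <- c("scan_id", "site_id", "patient_id", "point_id",
                      "analyst_id", "cautery_mode", "tissue_label",
                      "tumor_cell_pct", "adipose_pure", "pik3ca_status",
                      "hr_status")

#' Scan metadata table skeleton
#'
#' Builds (or completes) the per-scan metadata table used by
#' [reims_dataset()]. Any column not supplied is filled with its default:
#' `tissue_label = "unassigned"`, `pik3ca_status = "unknown"`,
#' `hr_status = "unknown"`, `adipose_pure = NA`, everything else `NA`.
#' `tumor_cell_pct` is the pathology-assessed percentage of tumour cells
#' surrounding the sampling point; `NA` means not annotated (never 0, which
#' is a meaningful value). `adipose_pure` records whether a 0% point is
#' 100% normal breast adipose (required for a "normal" label).
#'
#' @param scan_id Character vector of scan identifiers (required).
#' @param ... Further metadata columns, recycled to `length(scan_id)`.
#' @return A data.frame with one row per scan.
#' @export
scan_metadata <- function(scan_id, ...) {
  n <- length(scan_id)
  out <- data.frame(scan_id = as.character(scan_id),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  bad <- setdiff(names(extra), metadata_columns)
  if (length(bad)) stop("unknown metadata column(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(extra)) {
    if (is.null(extra[[nm]])) next
    out[[nm]] <- rep(extra[[nm]], length.out = n)
  }
  defaults <- list(site_id = NA_character_, patient_id = NA_character_,
                   point_id = NA_character_, analyst_id = NA_character_,
                   cautery_mode = NA_character_, tissue_label = "unassigned",
                   tumor_cell_pct = NA_real_, adipose_pure = NA,
                   pik3ca_status = "unknown", hr_status = "unknown")
  for (nm in names(defaults)) {
    if (is.null(out[[nm]])) out[[nm]] <- rep(defaults[[nm]], n)
  }
  bad_pct <- !is.na(out$tumor_cell_pct) &
    (out$tumor_cell_pct < 0 | out$tumor_cell_pct > 100)
  if (any(bad_pct)) stop("tumor_cell_pct must lie in [0, 100]")
  if (!all(out$cautery_mode %in% c("cut", "coag", NA_character_))) {
    stop("cautery_mode must be 'cut' or 'coag'")
  }
  out[, metadata_columns]
}

#' Labeled collection of REIMS scans
#'
#' The container every pipeline stage consumes: a list of
#' [reims_spectrum()] objects plus a metadata row per scan. The key
#' (site_id, patient_id, point_id, scan_id) must be unique.
#'
#' @param spectra List of `reims_spectrum` objects.
#' @param meta Metadata data.frame as built by [scan_metadata()]; row order
#'   must match `spectra`.
#' @param provenance Character vector of free-text processing log lines.
#' @return An object of class `reims_dataset`.
#' @export
reims_dataset <- function(spectra, meta, provenance = character()) {
  stopifnot(is.list(spectra))
  if (!all(vapply(spectra, inherits, logical(1), "reims_spectrum"))) {
    stop("all elements of 'spectra' must be reims_spectrum objects")
  }
  ids <- unname(vapply(spectra, `[[`, character(1), "scan_id"))
  meta <- scan_metadata(meta$scan_id,
                        site_id = meta$site_id, patient_id = meta$patient_id,
                        point_id = meta$point_id, analyst_id = meta$analyst_id,
                        cautery_mode = meta$cautery_mode,
                        tissue_label = meta$tissue_label,
                        tumor_cell_pct = meta$tumor_cell_pct,
                        adipose_pure = meta$adipose_pure,
                        pik3ca_status = meta$pik3ca_status,
                        hr_status = meta$hr_status)
  if (nrow(meta) != length(spectra)) {
    stop("one metadata row required per spectrum")
  }
  if (!identical(ids, meta$scan_id)) {
    stop("metadata scan_id order must match the spectra")
  }
  key <- paste(meta$site_id, meta$patient_id, meta$point_id, meta$scan_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("(site_id, patient_id, point_id, scan_id) must be unique")
  }
  names(spectra) <- ids
  structure(list(spectra = spectra, meta = meta, provenance = provenance),
            class = "reims_dataset")
}

#' @export
print.reims_dataset <- function(x, ...) {
  m <- x$meta
  cat("<reims_dataset>", length(x$spectra), "scans")
  if (length(x$spectra)) {
    cat(" |", length(unique(m$site_id)), "site(s),",
        length(unique(paste(m$site_id, m$patient_id))), "patient(s),",
        length(unique(paste(m$site_id, m$patient_id, m$point_id))),
        "sampling point(s)\n")
    print(table(tissue = m$tissue_label, mode = m$cautery_mode))
  } else cat("\n")
  invisible(x)
}

#' @export
length.reims_dataset <- function(x) length(x$spectra)

#' Subset a dataset by scan index or logical mask
#'
#' @param dataset A `reims_dataset`.
#' @param i Integer or logical index over scans.
#' @return The subsetted `reims_dataset`.
#' @export
subset_scans <- function(dataset, i) {
  stopifnot(inherits(dataset, "reims_dataset"))
  if (is.logical(i)) i <- which(i)
  reims_dataset(dataset$spectra[i],
                dataset$meta[i, , drop = FALSE],
                dataset$provenance)
}

log_provenance <- function(dataset, msg) {
  dataset$provenance <- c(dataset$provenance,
                          paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                 " ", msg))
  dataset
}
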