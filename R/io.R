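#' Read a peak-list file into a dataset
#'
#' Two open dialects are supported. `csv_peaklist` is a long-format CSV
#' with one row per peak and header `scan_id,mz,intensity`; per-scan
#' metadata comes either from a JSON sidecar at `<path>.meta.json` (keyed
#' by scan_id, preferred) or from repeated metadata columns in the CSV
#' itself. `jsonl` holds one JSON object per line with fields `scan_id`,
#' `mz`, `intensity`, `lockmass_shift` and `meta`.
#'
#' A missing `tumor_cell_pct` is serialized as an empty field / JSON null
#' and read back as `NA` — never as 0, which means a genuinely pure-normal
#' point.
#'
#' @param path File to read.
#' @param format `"csv_peaklist"` or `"jsonl"`.
#' @return A [reims_dataset()] with scans in file order.
#' @seealso [write_peaklist()]
#' @export
read_peaklist <- function(path, format = c("csv_peaklist", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") return(read_peaklist_jsonl(path))

  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("scan_id", "mz", "intensity")) {
    if (is.null(tab[[col]])) {
      stop("peak-list format error: missing required column '", col, "'")
    }
  }
  tab$scan_id <- as.character(tab$scan_id)
  ids <- unique(tab$scan_id)
  sidecar <- paste0(path, ".meta.json")
  meta_list <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = FALSE)
  } else NULL

  spectra <- vector("list", length(ids))
  meta_rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- tab[tab$scan_id == ids[k], , drop = FALSE]
    if (nrow(rows) > 1L && any(diff(rows$mz) <= 0)) {
      stop("peak-list data error: non-ascending m/z within scan '",
           ids[k], "'")
    }
    mrec <- if (!is.null(meta_list)) meta_list[[ids[k]]] else
      as.list(rows[1L, intersect(metadata_columns, names(rows)),
                   drop = FALSE])
    mrec <- mrec[!vapply(mrec, is.null, logical(1))]
    shift <- mrec$lockmass_shift
    mrec$lockmass_shift <- NULL
    spectra[[k]] <- reims_spectrum(ids[k], rows$mz, rows$intensity,
                                   if (is.null(shift)) NA_real_ else
                                     as.numeric(shift))
    mrec$scan_id <- ids[k]
    meta_rows[[k]] <- do.call(scan_metadata, normalize_meta_record(mrec))
  }
  reims_dataset(spectra, do.call(rbind, meta_rows),
                provenance = paste0("read_peaklist(", format, "): ", path))
}

normalize_meta_record <- function(mrec) {
  mrec <- mrec[names(mrec) %in% metadata_columns]
  if (!is.null(mrec$tumor_cell_pct)) {
    p <- mrec$tumor_cell_pct
    mrec$tumor_cell_pct <- if (is.null(p) || length(p) == 0L || is.na(p))
      NA_real_ else as.numeric(p)
  }
  if (!is.null(mrec$adipose_pure)) {
    mrec$adipose_pure <- as.logical(mrec$adipose_pure)
  }
  mrec
}

read_peaklist_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  spectra <- vector("list", length(lines))
  meta_rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[k], simplifyVector = TRUE)
    if (is.null(rec$scan_id)) {
      stop("peak-list format error: missing required column 'scan_id'")
    }
    mzk <- as.numeric(unlist(rec$mz))
    if (length(mzk) > 1L && any(diff(mzk) <= 0)) {
      stop("peak-list data error: non-ascending m/z within scan '",
           rec$scan_id, "'")
    }
    shift <- if (is.null(rec$lockmass_shift)) NA_real_ else
      as.numeric(rec$lockmass_shift)
    spectra[[k]] <- reims_spectrum(as.character(rec$scan_id), mzk,
                                   as.numeric(unlist(rec$intensity)), shift)
    mrec <- as.list(rec$meta)
    mrec$scan_id <- as.character(rec$scan_id)
    meta_rows[[k]] <- do.call(scan_metadata, normalize_meta_record(mrec))
  }
  reims_dataset(spectra, do.call(rbind, meta_rows),
                provenance = paste0("read_peaklist(jsonl): ", path))
}

#' Write a dataset as a peak-list file
#'
#' Inverse of [read_peaklist()]: `read_peaklist(write_peaklist(d, p), f)`
#' reproduces `d` exactly (m/z and intensities are written with 17
#' significant digits so doubles round-trip bit-for-bit).
#'
#' @param dataset A [reims_dataset()].
#' @param path Output file.
#' @param format `"csv_peaklist"` (writes a `<path>.meta.json` sidecar) or
#'   `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(dataset, path,
                           format = c("csv_peaklist", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "reims_dataset"))
  if (format == "jsonl") {
    lines <- vapply(seq_along(dataset$spectra), function(k) {
      s <- dataset$spectra[[k]]
      m <- as.list(dataset$meta[k, setdiff(metadata_columns, "scan_id")])
      jsonlite::toJSON(list(scan_id = s$scan_id, mz = s$mz,
                            intensity = s$intensity,
                            lockmass_shift = s$lockmass_shift, meta = m),
                       auto_unbox = TRUE, digits = NA, na = "null")
    }, character(1))
    writeLines(lines, path)
    return(invisible(path))
  }
  rows <- lapply(dataset$spectra, function(s) {
    data.frame(scan_id = rep(s$scan_id, length(s$mz)),
               mz = sprintf("%.17g", s$mz),
               intensity = sprintf("%.17g", s$intensity),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scan_id = character(), mz = character(),
               intensity = character())
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta_list <- list()
  for (k in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[k]]
    m <- as.list(dataset$meta[k, setdiff(metadata_columns, "scan_id")])
    m$lockmass_shift <- s$lockmass_shift
    meta_list[[s$scan_id]] <- m
  }
  jsonlite::write_json(meta_list, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
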