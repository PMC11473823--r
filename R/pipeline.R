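#' End-to-end analysis pipeline
#'
#' Runs the full multi-site workflow on a simulated cohort: cohort
#' generation, preprocessing (background subtraction, lockmass
#' correction, QC, binning, TIC normalization, label assignment),
#' PCA/LDA cross-validation under the three fold schemes, inter-site
#' variability metrics, classification of sub-threshold (excluded)
#' sampling points, sparse feature selection with a targeted model, and
#' the fatty-acid profile / ratio / channel-classifier analyses. Every
#' table is written as CSV under `out_dir` together with a JSON manifest
#' recording the seed, package version and a hash of the configuration;
#' rerunning with the same configuration reproduces the numeric tables
#' byte for byte.
#'
#' @param config Named list (unknown keys are rejected) with optional
#'   entries: `seed` (integer, default 1), `out_dir` (default a fresh
#'   temporary directory), `cohort` (a [cohort_config()] or argument list
#'   for one), `preprocess` (a [preprocess_config()] or argument list),
#'   `max_pca` (default 25), `knn_k` (default 5), `feature_cost`
#'   (default 500), `n_targeted` (bins kept for the targeted model,
#'   default 11), `channel_folds` (default 5). Alternatively a path to a
#'   YAML or JSON file with the same structure.
#' @return An object of class `reims_report`: a list with the fitted
#'   models, CV results, variability tables, FA analyses, exclusion
#'   accounting, `files` (paths written) and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  known <- c("seed", "out_dir", "cohort", "preprocess", "max_pca", "knn_k",
             "feature_cost", "n_targeted", "channel_folds")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("config validation error: unknown key(s): ",
         paste(bad, collapse = ", "))
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("reims_report_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- config$cohort %||% list()
  if (!inherits(cohort, "cohort_config")) {
    cohort$seed <- cohort$seed %||% seed
    cohort <- do.call(cohort_config, cohort)
  }
  pp <- config$preprocess %||% list()
  if (!inherits(pp, "preprocess_config")) {
    pp <- do.call(preprocess_config, pp)
  }
  max_pca <- config$max_pca %||% 25
  knn_k <- config$knn_k %||% 5
  feature_cost <- config$feature_cost %||% 500
  n_targeted <- config$n_targeted %||% 11
  channel_folds <- config$channel_folds %||% 5

  files <- character()
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    files[[name]] <<- path
    path
  }

  # --- simulate -------------------------------------------------------
  sim <- simulate_cohort(cohort)
  message("simulate: ", length(sim$dataset), " scans from ",
          length(cohort$sites), " site(s)")

  # --- preprocess -----------------------------------------------------
  prep <- preprocess_dataset(sim$dataset, pp)
  message("preprocess: ", nrow(prep$x), " scans kept, ",
          length(prep$excluded$spectra), " excluded by QC")
  labeled <- prep$meta$tissue_label %in% c("tumor", "normal")
  x <- prep$x[labeled, , drop = FALSE]
  meta <- prep$meta[labeled, , drop = FALSE]
  emit(prep$reasons, "qc_exclusions.csv")
  emit(data.frame(label = names(table(prep$meta$tissue_label)),
                  scans = as.integer(table(prep$meta$tissue_label))),
       "label_accounting.csv")

  # --- classify / cross-validate -------------------------------------
  model <- reims_pcalda(x, meta$tissue_label, max_pca = max_pca)
  cv <- list()
  rate_rows <- list()
  for (scheme in c("single_site", "leave_site_out", "leave_patient_out")) {
    cv[[scheme]] <- cross_validate(x, meta$tissue_label, meta$site_id,
                                   meta$patient_id, scheme = scheme,
                                   max_pca = max_pca)
    r <- cv[[scheme]]$rates
    rate_rows[[scheme]] <- data.frame(scheme = scheme, ccr_pct = r["ccr"],
                                      fn_pct = r["fn_rate"],
                                      fp_pct = r["fp_rate"],
                                      row.names = NULL)
    cmtab <- as.data.frame(as.table(cv[[scheme]]$pooled$counts))
    names(cmtab) <- c("true", "predicted", "n")
    emit(cmtab, paste0("confusion_", scheme, ".csv"))
  }
  emit(do.call(rbind, rate_rows), "cv_rates.csv")
  message("crossval: leave-site-out CCR ",
          sprintf("%.2f%%", cv$leave_site_out$rates["ccr"]),
          ", leave-patient-out CCR ",
          sprintf("%.2f%%", cv$leave_patient_out$rates["ccr"]))

  # --- sub-threshold (excluded) sampling points -----------------------
  excl_idx <- prep$meta$tissue_label == "excluded"
  excluded_points <- NULL
  if (any(excl_idx)) {
    pred <- predict(model, prep$x[excl_idx, , drop = FALSE])
    by_point <- split(pred$label == "tumor",
                      prep$meta$point_id[excl_idx])
    point_hit <- vapply(by_point, function(v) mean(v) >= 0.5, logical(1))
    excluded_points <- data.frame(
      n_points = length(by_point),
      pct_recognized_tumor = 100 * mean(point_hit),
      n_outlier_scans = sum(pred$outlier))
    emit(excluded_points, "excluded_point_classification.csv")
  }

  # --- variability ----------------------------------------------------
  sim_rep <- similarity_report(x, meta$site_id)
  emit(sim_rep, "similarity_by_site.csv")
  knn_acc <- knn_site_accuracy(x, meta$site_id, k = knn_k)
  volc <- volcano(x, meta$tissue_label, contrast = c("normal", "tumor"))
  emit(volc[order(volc$p), ][seq_len(min(50, nrow(volc))), ],
       "volcano_top50.csv")
  message(sprintf("variability: KNN site accuracy %.1f%%", 100 * knn_acc))

  # --- feature selection + targeted model -----------------------------
  sel <- l1_feature_select(x, meta$tissue_label, cost = feature_cost,
                           bin_centers = prep$bin_centers)
  emit(sel, "selected_features.csv")
  targeted <- NULL
  targeted_rates <- NULL
  if (nrow(sel) >= 2) {
    bins <- sel$bin[seq_len(min(n_targeted, nrow(sel)))]
    tcv <- cross_validate(x[, bins, drop = FALSE], meta$tissue_label,
                          meta$site_id, meta$patient_id,
                          scheme = "leave_patient_out", max_pca = max_pca)
    targeted <- targeted_model(x, meta$tissue_label, bins,
                               max_pca = max_pca)
    targeted_rates <- tcv$rates
  }

  # --- fatty-acid analyses --------------------------------------------
  kept <- prep$kept
  lab_keep <- kept$meta$tissue_label %in% c("tumor", "normal")
  prof <- t(vapply(kept$spectra[lab_keep],
                   function(s) as.numeric(extract_fa_profile(s)),
                   numeric(6)))
  colnames(prof) <- names(.fa_channel_mz)
  fa_meta <- kept$meta[lab_keep, , drop = FALSE]
  emit(cbind(fa_meta[, c("scan_id", "site_id", "tissue_label",
                         "pik3ca_status")], as.data.frame(prof)),
       "fa_profiles.csv")
  ratios <- t(apply(prof, 1, function(p)
    suppressWarnings(fa_ratios(stats::setNames(p, colnames(prof))))))
  emit(cbind(fa_meta[, c("scan_id", "tissue_label", "pik3ca_status")],
             as.data.frame(ratios)), "fa_ratios.csv")

  channel_cv <- NULL
  tum <- fa_meta$tissue_label == "tumor" &
    fa_meta$pik3ca_status %in% c("WT", "Mut")
  if (sum(tum) > 0 &&
      all(table(factor(fa_meta$pik3ca_status[tum],
                       levels = c("WT", "Mut"))) >= channel_folds)) {
    channel_cv <- channel_crossval(prof[tum, , drop = FALSE],
                                   fa_meta$pik3ca_status[tum],
                                   folds = channel_folds, seed = seed)
    emit(data.frame(accuracy = channel_cv$accuracy,
                    sensitivity = channel_cv$sensitivity,
                    specificity = channel_cv$specificity),
         "channel_cv.csv")
    message(sprintf("fa: channel-classifier CV accuracy %.1f%%",
                    100 * channel_cv$accuracy))
  }
  box <- tukey_box_stats(ratios[, "products/FA(18:2)"]
                         [is.finite(ratios[, "products/FA(18:2)"])])

  # --- manifest -------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(serializable_config(cohort, pp, seed, max_pca,
                                           knn_k, feature_cost,
                                           n_targeted, channel_folds),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("reims")),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_scans_simulated = length(sim$dataset),
                   n_scans_kept = nrow(prep$x),
                   n_scans_modeled = nrow(x),
                   tables = names(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  files[["manifest.json"]] <- file.path(out_dir, "manifest.json")

  structure(list(out_dir = out_dir, seed = seed, truth = sim$truth,
                 preprocess = prep[c("bin_centers", "reasons")],
                 model = model, cv = cv, excluded_points = excluded_points,
                 similarity = sim_rep, knn_site_accuracy = knn_acc,
                 volcano = volc, selected_features = sel,
                 targeted = targeted, targeted_rates = targeted_rates,
                 fa_profiles = prof, fa_ratios = ratios,
                 fa_box = box, channel_cv = channel_cv,
                 files = files, manifest = manifest),
            class = "reims_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

serializable_config <- function(cohort, pp, seed, max_pca, knn_k,
                                feature_cost, n_targeted, channel_folds) {
  list(seed = seed, max_pca = max_pca, knn_k = knn_k,
       feature_cost = feature_cost, n_targeted = n_targeted,
       channel_folds = channel_folds,
       preprocess = unclass(pp),
       cohort = list(
         seed = cohort$seed, preset = cohort$preset,
         sites = lapply(cohort$sites, unclass),
         patients_per_site = cohort$patients_per_site,
         points_per_patient = cohort$points_per_patient,
         scans_per_point = cohort$scans_per_point,
         mode_mix = cohort$mode_mix, tumor_fraction = cohort$tumor_fraction,
         pik3ca_mut_fraction = cohort$pik3ca_mut_fraction,
         fa_effect_sizes = as.list(cohort$fa_effect_sizes)))
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' @export
print.reims_report <- function(x, ...) {
  cat("REIMS pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  scans modeled:", x$manifest$n_scans_modeled, "of",
      x$manifest$n_scans_simulated, "simulated\n")
  for (scheme in names(x$cv)) {
    r <- x$cv[[scheme]]$rates
    cat(sprintf("  %-18s CCR %6.2f%%  FN %5.2f%%  FP %5.2f%%\n", scheme,
                r["ccr"], r["fn_rate"], r["fp_rate"]))
  }
  cat(sprintf("  KNN site accuracy: %.1f%%\n", 100 * x$knn_site_accuracy))
  cat("  selected features:", nrow(x$selected_features), "bins\n")
  if (!is.null(x$channel_cv)) {
    cat(sprintf("  PIK3CA channel CV: acc %.1f%%, sens %.1f%%, spec %.1f%%\n",
                100 * x$channel_cv$accuracy, 100 * x$channel_cv$sensitivity,
                100 * x$channel_cv$specificity))
  }
  cat("  outputs:", x$out_dir, "\n")
  invisible(x)
}
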