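#' Sparse (l1) feature selection over binned spectra
#'
#' Fits an l1-penalized linear separator between two classes and returns
#' the bins with non-zero weight, ranked by absolute weight. The solver
#' is lasso-penalized logistic regression (`glmnet`) at the single
#' penalty `lambda = 1 / (n * cost)`, so larger `cost` means weaker
#' regularization and a larger selected set, mirroring the cost
#' parameter of margin-based sparse linear classifiers
#' (the reference workflow uses `cost = 500`). Deterministic: the fit
#' involves no randomness. Because the l1 optimum is non-unique over
#' exactly identical columns, duplicate columns in the selection are
#' reported once, with their combined weight, on the lowest bin index.
#'
#' @param x Matrix of binned spectra (scans in rows).
#' @param labels Two-class label per scan, at least 5 samples per class.
#' @param cost Inverse-regularization cost (> 0), default 500.
#' @param bin_centers Optional numeric bin centres (Da), enables
#'   `mass_range` and m/z output.
#' @param mass_range Optional `c(lo, hi)` restriction (Da) applied before
#'   fitting.
#' @return data.frame ranked by `|weight|`: columns `bin` (column index
#'   into `x`), `mz` (if centres supplied), `weight`, `enriched_in` (the
#'   class the bin is relatively abundant in).
#' @export
l1_feature_select <- function(x, labels, cost = 500, bin_centers = NULL,
                              mass_range = NULL) {
  stopifnot(cost > 0)
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("feature selection needs exactly 2 classes")
  if (any(table(labels) < 5L)) stop("need at least 5 samples per class")
  cols <- seq_len(ncol(x))
  if (!is.null(mass_range)) {
    if (is.null(bin_centers)) stop("mass_range requires bin_centers")
    cols <- which(bin_centers >= mass_range[1] & bin_centers <= mass_range[2])
  }
  xs <- x[, cols, drop = FALSE]
  y <- as.integer(labels == cls[2])
  lambda <- 1 / (nrow(xs) * cost)
  # warm-started path down to the target penalty (coordinate descent is
  # unreliable when dropped straight onto a single small lambda)
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / nrow(xs)
  lmax <- max(lmax * 1.05, lambda * 1.001)
  lams <- exp(seq(log(lmax), log(lambda), length.out = 50))
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                        lambda = lams, standardize = FALSE,
                        maxit = 1e6)
  w <- as.numeric(fit$beta[, ncol(fit$beta)])
  nz <- which(w != 0)
  if (length(nz) > 1L) {
    # the l1 optimum is non-unique over exactly identical columns; report
    # each duplicate group once, with its combined weight, on the lowest
    # bin index
    key <- apply(xs[, nz, drop = FALSE], 2, paste, collapse = "\r")
    first <- match(key, key)
    for (i in which(first != seq_along(nz))) {
      w[nz[first[i]]] <- w[nz[first[i]]] + w[nz[i]]
      w[nz[i]] <- 0
    }
    nz <- which(w != 0)
  }
  o <- nz[order(abs(w[nz]), decreasing = TRUE)]
  out <- data.frame(bin = cols[o], weight = w[o],
                    enriched_in = ifelse(w[o] > 0, cls[2], cls[1]),
                    stringsAsFactors = FALSE)
  if (!is.null(bin_centers)) out$mz <- bin_centers[cols[o]]
  out
}

#' Refit the PCA/LDA classifier on a selected bin subset
#'
#' Same training and evaluation contract as [reims_pcalda()], restricted
#' to the given bins — the "targeted ion" model built from a handful of
#' differentially abundant species instead of the full mass range.
#'
#' @param x Full binned matrix (scans in rows).
#' @param labels Class per scan.
#' @param bins Column indices of the selected bins (at least 1).
#' @param max_pca Passed to [reims_pcalda()].
#' @return A `reims_pcalda` fit carrying `attr(, "bins")`.
#' @export
targeted_model <- function(x, labels, bins, max_pca = 25) {
  x <- as.matrix(x)
  if (length(bins) < 1L) stop("at least one selected bin required")
  if (any(bins < 1 | bins > ncol(x))) {
    stop("selected bin outside the grid")
  }
  fit <- reims_pcalda(x[, bins, drop = FALSE], labels, max_pca)
  attr(fit, "bins") <- bins
  fit
}

#' Extract the six-channel fatty-acid profile of a scan
#'
#' Reads the deprotonated omega-6 fatty-acid ions FA(18:2) m/z 279.23,
#' FA(20:2) 307.26, FA(20:3) 305.25, FA(20:4, arachidonic) 303.23,
#' FA(22:4) 331.26 and FA(22:5) 329.25 from a lockmass-corrected peak
#' list: each channel is the maximum intensity within `tolerance` of its
#' reference m/z, and the profile is normalized to the channel sum.
#'
#' @param spectrum A [reims_spectrum()] covering the m/z 250-350 region.
#' @param tolerance Channel half-window (Da), default 0.1 (the binning
#'   resolution).
#' @return Named numeric vector of the six channels (class `fa_profile`)
#'   with attributes `normalized` and `valid`; an all-zero profile is
#'   returned unnormalized with `valid = FALSE`.
#' @export
extract_fa_profile <- function(spectrum, tolerance = 0.1) {
  stopifnot(inherits(spectrum, "reims_spectrum"), tolerance > 0)
  refs <- .fa_channel_mz
  ch <- vapply(refs, function(r) {
    w <- which(abs(spectrum$mz - r) <= tolerance)
    if (length(w)) max(spectrum$intensity[w]) else 0
  }, numeric(1))
  s <- sum(ch)
  valid <- s > 0
  if (valid) ch <- ch / s
  structure(ch, class = "fa_profile", normalized = valid, valid = valid)
}

#' Omega-6 fatty-acid metabolic ratios
#'
#' Three ratio families over a six-channel FA profile: each channel
#' downstream of arachidonic acid divided by FA(20:4) (arachidonic
#' elongation products FA(22:4), FA(22:5)); FA(20:2) over its precursor
#' FA(18:2) (direct elongation); and the sum of all five FA(18:2)
#' products over FA(18:2) itself (overall flux through the omega-6
#' pathway). All ratios are invariant to rescaling of the profile; a zero
#' denominator yields `NA` with the reason recorded in
#' `attr(, "undefined")`.
#'
#' @param profile An `fa_profile` (normalized or not) or named numeric
#'   vector over the six channels.
#' @return Named numeric vector: `FA(22:4)/FA(20:4)`,
#'   `FA(22:5)/FA(20:4)`, `FA(20:2)/FA(18:2)`, `products/FA(18:2)`.
#' @export
fa_ratios <- function(profile) {
  ch <- as.numeric(profile)
  names(ch) <- names(profile)
  need <- names(.fa_channel_mz)
  if (!all(need %in% names(ch))) {
    stop("profile must carry the six named FA channels")
  }
  aa <- ch[["FA(20:4)"]]
  la <- ch[["FA(18:2)"]]
  products <- sum(ch[c("FA(20:2)", "FA(20:3)", "FA(20:4)", "FA(22:4)",
                       "FA(22:5)")])
  out <- c("FA(22:4)/FA(20:4)" = if (aa > 0) ch[["FA(22:4)"]] / aa else
             NA_real_,
           "FA(22:5)/FA(20:4)" = if (aa > 0) ch[["FA(22:5)"]] / aa else
             NA_real_,
           "FA(20:2)/FA(18:2)" = if (la > 0) ch[["FA(20:2)"]] / la else
             NA_real_,
           "products/FA(18:2)" = if (la > 0) products / la else NA_real_)
  undef <- names(out)[is.na(out)]
  if (length(undef)) {
    attr(out, "undefined") <- paste0(undef, ": zero denominator")
  }
  out
}

#' Fit the Gaussian channel (median/SD) subtype classifier
#'
#' For every class and FA channel, stores the median and standard
#' deviation of the training profiles; a new profile's class likelihood
#' is the product of the six Gaussian channel densities (independence
#' across channels). The SD is floored at `1e-6` of the class-channel
#' median (absolute `1e-9` when the median is 0) so degenerate classes
#' keep finite densities.
#'
#' @param profiles Matrix of FA profiles (samples in rows, the six named
#'   channels in columns), or a list of `fa_profile`s.
#' @param labels Class per profile; at least 3 profiles per class.
#' @return An object of class `reims_channel` with `location` and `scale`
#'   matrices (class x channel) and `class_labels`.
#' @seealso [predict.reims_channel()], [channel_crossval()]
#' @export
channel_fit <- function(profiles, labels) {
  profiles <- profiles_matrix(profiles)
  labels <- as.character(labels)
  stopifnot(nrow(profiles) == length(labels))
  counts <- table(labels)
  if (any(counts < 3L)) {
    stop("fit error: every class needs at least 3 profiles (",
         paste(names(counts)[counts < 3], collapse = ", "), ")")
  }
  classes <- sort(names(counts))
  loc <- t(vapply(classes, function(cl)
    apply(profiles[labels == cl, , drop = FALSE], 2, stats::median),
    numeric(ncol(profiles))))
  sc <- t(vapply(classes, function(cl)
    apply(profiles[labels == cl, , drop = FALSE], 2, stats::sd),
    numeric(ncol(profiles))))
  floor_ <- pmax(1e-6 * abs(loc), 1e-9)
  sc <- pmax(sc, floor_)
  dimnames(loc) <- dimnames(sc) <- list(classes, colnames(profiles))
  structure(list(location = loc, scale = sc, class_labels = classes,
                 counts = as.integer(counts[classes])),
            class = "reims_channel")
}

profiles_matrix <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- do.call(rbind, lapply(profiles, as.numeric))
    colnames(profiles) <- names(.fa_channel_mz)
  }
  profiles <- as.matrix(profiles)
  if (is.null(colnames(profiles))) {
    colnames(profiles) <- names(.fa_channel_mz)
  }
  profiles
}

#' Classify FA profiles with a fitted channel model
#'
#' Per-class log-likelihood is the sum over channels of the Gaussian
#' log-density with that class's (median, SD); the argmax wins, with
#' exact ties broken toward the lexicographically first class and
#' flagged.
#'
#' @param object A [channel_fit()] model.
#' @param newdata One profile (vector) or a matrix of profiles in rows.
#' @param ... Unused.
#' @return data.frame: `label`, `tie`, one `loglik_<class>` column per
#'   class.
#' @export
predict.reims_channel <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- profiles_matrix(newdata)
  if (!all(is.finite(newdata))) stop("invalid profile: non-finite values")
  cls <- object$class_labels
  ll <- vapply(cls, function(cl) {
    rowSums(matrix(stats::dnorm(t(newdata), object$location[cl, ],
                                object$scale[cl, ], log = TRUE),
                   nrow = nrow(newdata), byrow = TRUE))
  }, numeric(nrow(newdata)))
  ll <- matrix(ll, nrow = nrow(newdata), dimnames = list(NULL, cls))
  best <- apply(ll, 1, function(r) which(r == max(r))[1])
  tie <- apply(ll, 1, function(r) sum(r == max(r)) > 1L)
  out <- data.frame(label = cls[best], tie = tie, stringsAsFactors = FALSE)
  for (cl in cls) out[[paste0("loglik_", cl)]] <- ll[, cl]
  out
}

#' @export
print.reims_channel <- function(x, ...) {
  cat("Gaussian channel classifier,", length(x$class_labels), "classes x",
      ncol(x$location), "FA channels\n")
  cat("  classes:", paste(sprintf("%s (n=%d)", x$class_labels, x$counts),
                          collapse = ", "), "\n")
  cat("  channel medians:\n")
  print(round(x$location, 4))
  invisible(x)
}

#' Stratified k-fold cross-validation of the channel classifier
#'
#' Profiles are shuffled within class (reproducibly from `seed`) and
#' dealt into `folds` stratified folds; each fold is scored by the model
#' fitted on the others. Sensitivity is the recall of the positive class,
#' specificity the recall of the remaining class.
#'
#' @param profiles Profile matrix (samples x channels).
#' @param labels Class per profile; every class needs at least `folds`
#'   profiles.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param positive_class Class counted as positive (default `"Mut"`).
#' @return List: `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (a [reims_confusion()]), `fold_id` (assignment used).
#' @export
channel_crossval <- function(profiles, labels, folds = 5, seed = 1,
                             positive_class = "Mut") {
  profiles <- profiles_matrix(profiles)
  labels <- as.character(labels)
  stopifnot(nrow(profiles) == length(labels), folds >= 2)
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("every class needs at least as many profiles as folds")
  }
  classes <- sort(names(counts))
  set.seed(as.integer(seed))
  fold_id <- integer(length(labels))
  for (cl in classes) {
    i <- which(labels == cl)
    fold_id[i] <- (seq_along(i) %% folds) + 1L
    fold_id[i] <- fold_id[i][sample.int(length(i))]
  }
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- channel_fit(profiles[tr, , drop = FALSE], labels[tr])
    pred <- predict(fit, profiles[!tr, , drop = FALSE])
    truth <- labels[!tr]
    for (i in seq_along(truth)) {
      cm[truth[i], pred$label[i]] <- cm[truth[i], pred$label[i]] + 1
    }
  }
  acc <- sum(diag(cm)) / sum(cm)
  sens <- if (positive_class %in% classes)
    cm[positive_class, positive_class] / sum(cm[positive_class, ]) else
      NA_real_
  neg <- setdiff(classes, positive_class)
  spec <- if (length(neg))
    sum(diag(cm)[neg]) / sum(cm[neg, , drop = FALSE]) else NA_real_
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       confusion = reims_confusion(cm), fold_id = fold_id)
}

#' Tukey box-and-whisker statistics
#'
#' Quartiles by linear interpolation (R quantile type 7); whiskers extend
#' to the most extreme data points within 1.5 interquartile ranges of the
#' quartiles; points beyond those fences are listed individually.
#'
#' @param values Numeric vector, at least 4 values.
#' @return List of class `box_stats`: `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, `flagged` (values beyond the fences).
#' @export
tukey_box_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 flagged = sort(values[!inside])),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("box: Q1 %.4g | median %.4g | Q3 %.4g; whiskers [%.4g, %.4g]",
              x$q1, x$median, x$q3, x$whisker_low, x$whisker_high))
  if (length(x$flagged)) {
    cat("; flagged:", paste(signif(x$flagged, 4), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
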