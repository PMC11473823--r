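#' Fit a PCA/LDA tissue classifier
#'
#' Principal component analysis (at most `max_pca` components, fewer when
#' limited by feature count or sample size) followed by linear
#' discriminant analysis in PCA space with `n_classes - 1` discriminant
#' directions. The fitted object stores everything needed to score new
#' spectra without the training data: the feature mean, PCA loadings and
#' explained variance, LDA directions (scaled to unit pooled within-class
#' variance, so distances in discriminant space are in within-class SD
#' units), per-class centroids and spreads.
#'
#' Determinism: every PCA loading and LDA direction is oriented so its
#' largest-magnitude coefficient is positive; class labels are kept in
#' lexicographic order. A singular within-class scatter is
#' ridge-regularized with `epsilon = 1e-8 * trace/dim` (recorded on the
#' object).
#'
#' @param x Numeric matrix of TIC-normalized binned spectra, scans in
#'   rows.
#' @param labels Class label per row; at least two classes with at least
#'   two samples each.
#' @param max_pca Maximum number of PCA components (default 25).
#' @return An object of class `reims_pcalda` with components
#'   `feature_mean`, `pca_loadings`, `explained_variance`,
#'   `lda_directions`, `class_centroids`, `class_spread`, `class_labels`,
#'   `counts`, `ridge_epsilon`.
#' @seealso [predict.reims_pcalda()], [cross_validate()]
#' @export
reims_pcalda <- function(x, labels, max_pca = 25) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (!all(is.finite(x))) stop("features must be finite")
  counts <- table(labels)
  if (length(counts) < 2L) stop("fit error: need at least 2 classes")
  if (any(counts < 2L)) {
    stop("fit error: class with fewer than 2 samples: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  classes <- sort(names(counts))
  n <- nrow(x)

  k <- min(max_pca, ncol(x), n - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  keep <- pc$sdev[seq_len(k)] > max(pc$sdev[1], .Machine$double.eps) * 1e-8
  loadings <- pc$rotation[, keep, drop = FALSE]
  sdev <- pc$sdev[seq_len(k)][keep]
  # sign convention: largest-magnitude coefficient of each loading positive
  flip <- apply(loadings, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(loadings, 2, flip, `*`)
  z <- sweep(x, 2, pc$center) %*% loadings

  d <- ncol(z)
  gm <- colMeans(z)
  cls_means <- matrix(NA_real_, length(classes), d,
                      dimnames = list(classes, NULL))
  for (cl in classes) {
    cls_means[cl, ] <- colMeans(z[labels == cl, , drop = FALSE])
  }
  sw <- matrix(0, d, d)
  sb <- matrix(0, d, d)
  for (cl in classes) {
    zi <- z[labels == cl, , drop = FALSE]
    dev <- sweep(zi, 2, cls_means[cl, ])
    sw <- sw + crossprod(dev)
    dc <- cls_means[cl, ] - gm
    sb <- sb + nrow(zi) * tcrossprod(dc)
  }
  sw <- sw / (n - length(classes))
  eps <- 0
  if (rcond_sym(sw) < 1e-10) {
    eps <- 1e-8 * sum(diag(sw)) / d
    sw <- sw + diag(eps, d)
  }
  eg <- eigen(solve(sw, sb))
  ord <- order(Re(eg$values), decreasing = TRUE)
  ndir <- min(length(classes) - 1L, sum(Re(eg$values)[ord] > 1e-10 *
                                          max(Re(eg$values), 1e-300)))
  ndir <- max(ndir, 1L)
  w <- Re(eg$vectors[, ord[seq_len(ndir)], drop = FALSE])
  # scale each direction to unit pooled within-class variance
  for (j in seq_len(ndir)) {
    s2 <- drop(t(w[, j]) %*% sw %*% w[, j])
    w[, j] <- w[, j] / sqrt(s2)
  }
  flip <- apply(w, 2, function(v) sign(v[which.max(abs(v))]))
  w <- sweep(w, 2, flip, `*`)

  t_scores <- z %*% w
  centroids <- matrix(NA_real_, length(classes), ndir,
                      dimnames = list(classes, paste0("LD",
                                                      seq_len(ndir))))
  spread <- centroids
  for (cl in classes) {
    ti <- t_scores[labels == cl, , drop = FALSE]
    centroids[cl, ] <- colMeans(ti)
    spread[cl, ] <- pmax(apply(ti, 2, stats::sd), 1e-12)
  }

  structure(list(feature_mean = pc$center, pca_loadings = loadings,
                 explained_variance = sdev^2,
                 lda_directions = w, class_centroids = centroids,
                 class_spread = spread, class_labels = classes,
                 counts = as.integer(counts[classes]),
                 ridge_epsilon = eps, n_features = ncol(x),
                 feature_names = colnames(x),
                 var_explained_frac = sum(sdev^2) / sum(pc$sdev^2)),
            class = "reims_pcalda")
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Classify spectra with a fitted PCA/LDA model
#'
#' Projects spectra through the stored PCA loadings and LDA directions and
#' assigns each to the nearest class centroid in discriminant space. The
#' distance is already standardized (directions have unit pooled
#' within-class variance), and a spectrum farther than `outlier_sd`
#' standard deviations from its nearest centroid is flagged as an
#' outlier. Exact ties are broken toward the lexicographically first
#' class label and recorded.
#'
#' @param object A [reims_pcalda()] fit.
#' @param newdata Matrix of spectra on the model's grid (scans in rows),
#'   or a single numeric vector.
#' @param outlier_sd Outlier threshold in within-class SDs (default 5).
#' @param ... Unused.
#' @return A data.frame with columns `label`, `outlier`, `tie` and one
#'   `dist_<class>` column of standardized distances per class.
#' @export
predict.reims_pcalda <- function(object, newdata, outlier_sd = 5, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("dimension error: model expects ", object$n_features,
         " features, got ", ncol(newdata))
  }
  t_scores <- sweep(newdata, 2, object$feature_mean) %*%
    object$pca_loadings %*% object$lda_directions
  cls <- object$class_labels
  dists <- vapply(cls, function(cl) {
    sqrt(rowSums(sweep(t_scores, 2, object$class_centroids[cl, ])^2))
  }, numeric(nrow(t_scores)))
  dists <- matrix(dists, nrow = nrow(t_scores),
                  dimnames = list(NULL, cls))
  nearest <- apply(dists, 1, function(r) {
    i <- which(r == min(r))   # ties resolve to the first (lexicographic)
    i[1]
  })
  tie <- apply(dists, 1, function(r) sum(r == min(r)) > 1L)
  mind <- dists[cbind(seq_len(nrow(dists)), nearest)]
  out <- data.frame(label = cls[nearest], outlier = mind > outlier_sd,
                    tie = tie, stringsAsFactors = FALSE)
  for (cl in cls) out[[paste0("dist_", cl)]] <- dists[, cl]
  out
}

#' @export
print.reims_pcalda <- function(x, ...) {
  cat("PCA/LDA tissue classifier\n")
  cat("  classes:", paste(sprintf("%s (n=%d)", x$class_labels, x$counts),
                          collapse = ", "), "\n")
  cat("  PCA components:", ncol(x$pca_loadings),
      sprintf("(%.1f%% of variance)", 100 * x$var_explained_frac), "\n")
  cat("  LDA directions:", ncol(x$lda_directions), "\n")
  if (x$ridge_epsilon > 0) {
    cat("  within-class scatter ridge epsilon:",
        format(x$ridge_epsilon), "\n")
  }
  invisible(x)
}

#' @export
summary.reims_pcalda <- function(object, ...) {
  print(object)
  cat("  class centroids (discriminant space):\n")
  print(round(object$class_centroids, 3))
  cat("  per-class spread (SD along discriminants):\n")
  print(round(object$class_spread, 3))
  invisible(object)
}

#' Plot discriminant scores of training or new spectra
#'
#' For a two-class model this is a one-dimensional strip of LD1 scores by
#' class with the 5-SD outlier fences around each centroid.
#'
#' @param x A [reims_pcalda()] fit.
#' @param newdata Spectra matrix to project; labels taken from `labels`.
#' @param labels Optional class per row of `newdata` for coloring.
#' @param outlier_sd Fence width in SD units.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.reims_pcalda <- function(x, newdata, labels = NULL, outlier_sd = 5,
                              ...) {
  t_scores <- sweep(as.matrix(newdata), 2, x$feature_mean) %*%
    x$pca_loadings %*% x$lda_directions
  grp <- if (is.null(labels)) rep(1L, nrow(t_scores)) else
    as.integer(factor(labels, levels = x$class_labels))
  graphics::plot(t_scores[, 1], stats::runif(length(grp), grp - 0.1,
                                             grp + 0.1),
                 col = grp + 1, pch = 16,
                 xlab = "LD1 score", ylab = "class", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(x$class_labels),
                 labels = x$class_labels)
  for (cl in seq_along(x$class_labels)) {
    c1 <- x$class_centroids[cl, 1]
    graphics::abline(v = c(c1 - outlier_sd, c1 + outlier_sd), lty = 3,
                     col = cl + 1)
  }
  invisible(t_scores)
}

#' Confusion matrix container
#'
#' Counts indexed by (true class, predicted class), with a parallel matrix
#' of counts restricted to outlier-flagged spectra so rates can be
#' reported with outliers either retained in or excluded from the
#' denominator.
#'
#' @param counts Square matrix, rows = true class, columns = predicted.
#' @param outlier_counts Same shape; outlier-flagged spectra only.
#' @return An object of class `reims_confusion`.
#' @export
reims_confusion <- function(counts, outlier_counts = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (is.null(outlier_counts)) {
    outlier_counts <- matrix(0, nrow(counts), ncol(counts),
                             dimnames = dimnames(counts))
  }
  stopifnot(all(dim(outlier_counts) == dim(counts)),
            all(outlier_counts <= counts))
  structure(list(counts = counts, outlier_counts = outlier_counts),
            class = "reims_confusion")
}

#' @export
print.reims_confusion <- function(x, ...) {
  cat("Confusion matrix (true x predicted):\n")
  print(x$counts)
  if (sum(x$outlier_counts) > 0) {
    cat("outliers per true class:",
        paste(rowSums(x$outlier_counts), collapse = ", "), "\n")
  }
  r <- confusion_metrics(x)
  cat(sprintf("CCR %.2f%%", r["ccr"]))
  if (!is.na(r["fn_rate"])) cat(sprintf(", FN %.2f%%", r["fn_rate"]))
  if (!is.na(r["fp_rate"])) cat(sprintf(", FP %.2f%%", r["fp_rate"]))
  cat("\n")
  invisible(x)
}

#' Correct-classification, false-negative and false-positive rates
#'
#' For a two-class matrix with positive class "tumor": the correct
#' classification rate is the diagonal share of all evaluated spectra,
#' the false-negative rate the share of true tumor spectra predicted
#' normal, the false-positive rate the share of true normal spectra
#' predicted tumor. Rates are returned as unrounded percentages; an empty
#' class yields `NA` for its rate. With `exclude_outliers = TRUE` the
#' outlier-flagged spectra are removed from numerator and denominator.
#'
#' @param cm A [reims_confusion()], or a plain counts matrix
#'   (true x predicted).
#' @param positive_class Label of the positive (tumor) class.
#' @param exclude_outliers Drop outlier-flagged spectra from all counts.
#' @return Named numeric vector: `ccr`, `fn_rate`, `fp_rate` (percent).
#' @examples
#' cm <- matrix(c(69, 2, 1, 138), 2, byrow = TRUE,
#'              dimnames = list(c("tumor", "normal"),
#'                              c("tumor", "normal")))
#' confusion_metrics(cm)  # 98.57, 2.82, 0.72
#' @export
confusion_metrics <- function(cm, positive_class = "tumor",
                              exclude_outliers = FALSE) {
  if (!inherits(cm, "reims_confusion")) cm <- reims_confusion(cm)
  counts <- cm$counts
  if (exclude_outliers) counts <- counts - cm$outlier_counts
  total <- sum(counts)
  if (total <= 0) stop("confusion matrix has no evaluated spectra")
  ccr <- 100 * sum(diag(counts)) / total
  cls <- rownames(counts)
  fn <- fp <- NA_real_
  if (!is.null(cls) && positive_class %in% cls) {
    pos_tot <- sum(counts[positive_class, ])
    neg <- setdiff(cls, positive_class)
    neg_tot <- sum(counts[neg, , drop = FALSE])
    fn <- if (pos_tot > 0)
      100 * sum(counts[positive_class, neg, drop = FALSE]) / pos_tot else
        NA_real_
    fp <- if (neg_tot > 0)
      100 * sum(counts[neg, positive_class, drop = FALSE]) / neg_tot else
        NA_real_
  }
  c(ccr = ccr, fn_rate = fn, fp_rate = fp)
}

#' Cross-validated tissue classification
#'
#' Three fold schemes over the (site, patient) hierarchy:
#' `"single_site"` trains on one site's spectra and tests on all other
#' sites (one fold per training site); `"leave_site_out"` trains on all
#' but one site and tests the held-out site; `"leave_patient_out"` holds
#' out one patient at a time. No test spectrum's site (or patient) ever
#' appears in its fold's training set. Folds whose training set loses a
#' class entirely are skipped with a warning. Outliers (5-SD rule) are
#' retained in the pooled counts but tracked so rates can be computed on
#' outlier-excluded denominators too.
#'
#' @param x Matrix of TIC-normalized binned spectra (scans in rows).
#' @param labels True class per scan.
#' @param site,patient Site and patient identifier per scan.
#' @param scheme Fold scheme.
#' @param max_pca Passed to [reims_pcalda()].
#' @param outlier_sd Outlier threshold in SD units.
#' @return An object of class `reims_cv`: `scheme`, `folds` (list of
#'   per-fold [reims_confusion()] plus ids), `pooled` confusion matrix,
#'   `rates` and `rates_excl_outliers` (see [confusion_metrics()]).
#' @export
cross_validate <- function(x, labels, site, patient,
                           scheme = c("leave_site_out", "leave_patient_out",
                                      "single_site"),
                           max_pca = 25, outlier_sd = 5) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  labels <- as.character(labels)
  site <- as.character(site)
  patient <- as.character(patient)
  stopifnot(nrow(x) == length(labels), length(site) == length(labels),
            length(patient) == length(labels))
  if (scheme %in% c("leave_site_out", "single_site") &&
      length(unique(site)) < 2L) {
    stop("site-based schemes need at least 2 sites")
  }
  if (scheme == "leave_patient_out" && length(unique(patient)) < 2L) {
    stop("leave_patient_out needs at least 2 patients")
  }
  classes <- sort(unique(labels))
  folds <- switch(scheme,
    leave_site_out = lapply(sort(unique(site)), function(s)
      list(id = s, train = site != s, test = site == s)),
    single_site = lapply(sort(unique(site)), function(s)
      list(id = s, train = site == s, test = site != s)),
    leave_patient_out = lapply(sort(unique(patient)), function(p)
      list(id = p, train = patient != p, test = patient == p)))

  zero <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  pooled <- zero; pooled_out <- zero
  fold_results <- list()
  for (f in folds) {
    tr_lab <- labels[f$train]
    if (length(unique(tr_lab)) < length(classes) ||
        any(table(tr_lab) < 2)) {
      warning("fold '", f$id,
              "' skipped: training set lost a class (or has a singleton)")
      next
    }
    fit <- reims_pcalda(x[f$train, , drop = FALSE], tr_lab, max_pca)
    pred <- predict(fit, x[f$test, , drop = FALSE], outlier_sd = outlier_sd)
    cm <- zero; cm_out <- zero
    truth <- labels[f$test]
    for (i in seq_along(truth)) {
      cm[truth[i], pred$label[i]] <- cm[truth[i], pred$label[i]] + 1
      if (pred$outlier[i]) {
        cm_out[truth[i], pred$label[i]] <- cm_out[truth[i],
                                                  pred$label[i]] + 1
      }
    }
    pooled <- pooled + cm
    pooled_out <- pooled_out + cm_out
    unit <- if (scheme == "leave_patient_out") patient else site
    fold_results[[f$id]] <- list(id = f$id,
                                 confusion = reims_confusion(cm, cm_out),
                                 n_train = sum(f$train),
                                 n_test = sum(f$test),
                                 train_units = unique(unit[f$train]),
                                 test_units = unique(unit[f$test]))
  }
  if (length(fold_results) == 0L) stop("no usable folds")
  pooled_cm <- reims_confusion(pooled, pooled_out)
  structure(list(scheme = scheme, folds = fold_results, pooled = pooled_cm,
                 rates = confusion_metrics(pooled_cm),
                 rates_excl_outliers =
                   confusion_metrics(pooled_cm, exclude_outliers = TRUE)),
            class = "reims_cv")
}

#' @export
print.reims_cv <- function(x, ...) {
  cat("Cross-validation (", x$scheme, "), ", length(x$folds),
      " fold(s)\n", sep = "")
  print(x$pooled)
  invisible(x)
}
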