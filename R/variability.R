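#' Cosine similarity between spectra
#'
#' Inner product divided by the product of Euclidean norms. For
#' non-negative binned spectra the score lies in `[0, 1]`, reaching 1
#' exactly for proportional vectors (scale invariant). Errors on a zero
#' vector or mismatched grids.
#'
#' @param a,b `binned_spectrum` objects on the same grid, or plain numeric
#'   vectors of equal length.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "binned_spectrum")) a$values else as.numeric(a)
  vb <- if (inherits(b, "binned_spectrum")) b$values else as.numeric(b)
  if (inherits(a, "binned_spectrum") && inherits(b, "binned_spectrum")) {
    if (a$grid_start != b$grid_start || a$grid_end != b$grid_end ||
        a$bin_width != b$bin_width) {
      stop("spectra are on different grids")
    }
  }
  if (length(va) != length(vb)) stop("vectors of unequal length")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(va * vb) / (na * nb)
}

cosine_matrix <- function(x) {
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) stop("cosine similarity undefined for zero vector")
  tcrossprod(x / norms)
}

#' Within- and between-group spectral similarity summary
#'
#' Summarizes all pairwise cosine similarities within each group and
#' between each pair of groups (median and IQR), the standard way of
#' quantifying intra- vs inter-site (or mode, analyst, tissue)
#' reproducibility of REIMS spectra. Groups with a single spectrum are
#' skipped with a warning.
#'
#' @param x Matrix of binned spectra (scans in rows).
#' @param groups Grouping value per scan (site, tissue, mode, ...).
#' @param keep_pairs Return the raw pairwise scores as an attribute.
#' @return data.frame with columns `group1`, `group2`, `type`
#'   (`"within"`/`"between"`), `n_pairs`, `median`, `iqr`.
#' @export
similarity_report <- function(x, groups, keep_pairs = FALSE) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  stopifnot(nrow(x) == length(groups))
  tab <- table(groups)
  singletons <- names(tab)[tab < 2]
  if (length(singletons)) {
    warning("singleton group(s) skipped: ",
            paste(singletons, collapse = ", "))
  }
  gs <- sort(names(tab)[tab >= 2])
  cm <- cosine_matrix(x)
  rows <- list(); pairs <- list()
  for (i in seq_along(gs)) {
    for (j in i:length(gs)) {
      gi <- which(groups == gs[i]); gj <- which(groups == gs[j])
      if (i == j) {
        idx <- t(utils::combn(gi, 2))
        type <- "within"
      } else {
        idx <- as.matrix(expand.grid(gi, gj))
        type <- "between"
      }
      vals <- cm[idx]
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = gs[i], group2 = gs[j], type = type,
        n_pairs = length(vals), median = stats::median(vals),
        iqr = stats::IQR(vals), stringsAsFactors = FALSE)
      if (keep_pairs) pairs[[paste(gs[i], gs[j], sep = "|")]] <- vals
    }
  }
  out <- do.call(rbind, rows)
  if (keep_pairs) attr(out, "pairs") <- pairs
  out
}

#' Leave-one-out KNN site identification accuracy
#'
#' Classifies every spectrum by the majority site label of its `k`
#' nearest neighbours under cosine distance (self excluded); vote ties
#' are broken toward the single nearest neighbour's label. High accuracy
#' means spectra carry a recognizable site fingerprint.
#'
#' @param x Matrix of binned spectra (scans in rows).
#' @param site Site label per scan; every site needs at least `k + 1`
#'   spectra.
#' @param k Number of neighbours (default 5).
#' @return Leave-one-out accuracy as a fraction in `[0, 1]`.
#' @export
knn_site_accuracy <- function(x, site, k = 5) {
  x <- as.matrix(x)
  site <- as.character(site)
  n <- nrow(x)
  stopifnot(length(site) == n)
  if (k >= n) stop("parameter error: k must be smaller than the dataset")
  if (any(table(site) < k + 1)) {
    stop("every site needs at least k + 1 spectra")
  }
  d <- 1 - cosine_matrix(x)
  correct <- logical(n)
  for (i in seq_len(n)) {
    ord <- order(d[i, -i])
    nn <- (seq_len(n)[-i])[ord[seq_len(k)]]
    votes <- table(site[nn])
    top <- names(votes)[votes == max(votes)]
    pred <- if (length(top) == 1L) top else site[nn[1L]]
    correct[i] <- pred == site[i]
  }
  mean(correct)
}

#' Per-bin differential abundance (volcano) table
#'
#' Two-sample t statistics per bin between two groups of spectra, with
#' Welch's unequal-variance correction by default, two-tailed p-values
#' and the log2 ratio of group means. The fold change uses a pseudocount
#' of half the smallest positive bin value in the contrast so bins absent
#' from one group remain finite. Bins with zero variance in both groups
#' get `NA` p-values. No multiple-testing correction is applied by
#' default (significance is raw p < 0.05); set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param x Matrix of binned spectra (scans in rows).
#' @param groups Two-level grouping per scan.
#' @param contrast Character vector of the two levels `c(reference,
#'   comparison)`; fold changes are comparison over reference. Defaults
#'   to the sorted levels.
#' @param welch Use Welch's correction (default TRUE; FALSE pools
#'   variances).
#' @param alpha Significance level for the flag.
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame with one row per bin: `bin`, `mean_ref`,
#'   `mean_cmp`, `log2_fc`, `t`, `df`, `p`, `significant`.
#' @export
volcano <- function(x, groups, contrast = NULL, welch = TRUE,
                    alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (is.null(contrast)) contrast <- sort(unique(groups))
  stopifnot(length(contrast) == 2L, all(contrast %in% groups))
  a <- x[groups == contrast[1], , drop = FALSE]
  b <- x[groups == contrast[2], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least 2 spectra")
  }
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / (((va / na)^2) / (na - 1) + ((vb / nb)^2) / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  }
  zero_both <- va == 0 & vb == 0
  se2[zero_both] <- NA_real_   # p undefined; also silences 0/0 warnings
  df[zero_both] <- NA_real_
  tstat <- (mb - ma) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[zero_both] <- NA_real_
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  pos <- c(a[a > 0], b[b > 0])
  pseudo <- if (length(pos)) min(pos) / 2 else 0
  l2fc <- log2((mb + pseudo) / (ma + pseudo))
  l2fc[ma == mb] <- 0
  bins <- colnames(x)
  if (is.null(bins)) bins <- paste0("bin", seq_len(ncol(x)))
  data.frame(bin = bins, mean_ref = ma, mean_cmp = mb, log2_fc = l2fc,
             t = tstat, df = df, p = p,
             significant = !is.na(p) & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
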