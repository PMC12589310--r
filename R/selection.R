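#' Mann-Whitney U prefilter of a feature table
#'
#' Two-sided Mann-Whitney U test of each feature between the two label
#' classes; features with p below \code{alpha} survive. The exact null
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction) is used.
#'
#' @param features data.frame or matrix, subjects x features (numeric).
#' @param labels Binary vector (0/1 or logical), one per subject.
#' @param alpha Significance level in (0, 1).
#' @return data.frame with columns \code{feature}, \code{p}, restricted to
#'   survivors and sorted by ascending p; all tested p-values in
#'   \code{attr(, "all_p")}.
#' @export
mwu_prefilter <- function(features, labels, alpha = 0.05) {
  labels <- as.integer(as.logical(labels))
  stop_if(length(unique(labels)) < 2, "labels contain a single class")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  features <- as.data.frame(features)
  g1 <- labels == 1
  total_n <- length(labels)
  p <- vapply(features, function(x) {
    x <- as.numeric(x)
    has_ties <- anyDuplicated(x) > 0
    if (stats::sd(x) == 0) return(1)
    exact <- total_n <= 20 && !has_ties
    suppressWarnings(stats::wilcox.test(x[g1], x[!g1], exact = exact,
                                        correct = FALSE)$p.value)
  }, numeric(1))
  keep <- which(p < alpha)
  out <- data.frame(feature = names(features)[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_p") <- stats::setNames(p, names(features))
  out
}

#' Spearman redundancy pruning
#'
#' Greedy pass over features in ascending order of their stage-1 p-value
#' (ties broken lexicographically by name): a feature is dropped if its
#' absolute Spearman rank correlation with any already-retained feature
#' exceeds \code{cutoff}. A constant feature has undefined rank correlation,
#' which is treated as 0 (retained), unless it exactly duplicates an
#' already-retained constant feature.
#'
#' @param features data.frame, subjects x features.
#' @param cutoff Correlation magnitude above which the later feature is
#'   dropped (default 0.9).
#' @param priority Named numeric vector of p-values used for ordering
#'   (smaller = kept first); defaults to the column order.
#' @return Character vector of retained feature names.
#' @export
spearman_prune <- function(features, cutoff = 0.9, priority = NULL) {
  stop_if(cutoff <= 0 || cutoff > 1, "cutoff must be in (0, 1]")
  features <- as.data.frame(features)
  nm <- names(features)
  if (is.null(priority)) priority <- stats::setNames(seq_along(nm), nm)
  ord <- nm[order(priority[nm], nm)]
  kept <- character(0)
  kept_ranks <- list()
  for (f in ord) {
    x <- as.numeric(features[[f]])
    const_x <- stats::sd(x) == 0
    rx <- rank(x)
    drop <- FALSE
    for (k in kept) {
      y <- as.numeric(features[[k]])
      const_y <- stats::sd(y) == 0
      if (const_x || const_y) {
        ## undefined correlation: treated as 0 unless exact duplicates
        if (const_x && const_y && isTRUE(all.equal(x, y))) { drop <- TRUE; break }
        next
      }
      rho <- stats::cor(rx, kept_ranks[[k]])
      if (is.finite(rho) && abs(rho) > cutoff) { drop <- TRUE; break }
    }
    if (!drop) {
      kept <- c(kept, f)
      kept_ranks[[f]] <- rx
    }
  }
  kept
}

## Stratified, seeded fold assignment.
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(as.integer(seed))
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' LASSO selection with cross-validated lambda
#'
#' L1-penalized logistic regression over a descending 100-lambda path
#' (ratio 1e-3), with lambda chosen by minimal mean cross-validated
#' binomial deviance over seeded, class-stratified folds (the
#' \code{lambda.min} rule). Survivors are the features with nonzero
#' coefficients at the chosen lambda; coefficients are reported on the
#' standardized (unit-SD predictor) scale.
#'
#' @param features data.frame or matrix, subjects x features (>= 2
#'   features).
#' @param labels Binary labels.
#' @param n_folds Number of CV folds (>= 2, at most the minority-class
#'   count).
#' @param seed Integer seed for fold assignment.
#' @return data.frame with columns \code{feature}, \code{coefficient}
#'   (standardized scale); chosen lambda in \code{attr(, "lambda")}.
#' @export
lasso_select <- function(features, labels, n_folds = 10L, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  stop_if(length(unique(labels)) < 2, "labels contain a single class")
  n_min <- min(table(labels))
  stop_if(n_folds < 2 || n_folds > n_min,
          "n_folds must be >= 2 and at most the minority-class count")
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  stop_if(ncol(x) < 2, "need at least two features for the lasso path")
  foldid <- stratified_folds(labels, n_folds, seed)
  cvfit <- glmnet::cv.glmnet(x, labels, family = "binomial",
                             foldid = foldid, nlambda = 100,
                             lambda.min.ratio = 1e-3,
                             standardize = TRUE,
                             type.measure = "deviance")
  co <- stats::coef(cvfit, s = "lambda.min")
  co <- as.numeric(co)[-1]
  nz <- which(co != 0)
  sds <- apply(x, 2, stats::sd)
  out <- data.frame(feature = colnames(x)[nz],
                    coefficient = co[nz] * sds[nz],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lambda") <- cvfit$lambda.min
  out
}

#' Three-step feature-selection cascade
#'
#' Mann-Whitney prefilter (p < \code{alpha}, no multiplicity adjustment),
#' Spearman redundancy pruning (|rho| > \code{cutoff} drops the
#' larger-p feature), then LASSO with cross-validated lambda. The survivor
#' sets are nested: stage3 within stage2 within stage1.
#'
#' @param features Subjects x features table.
#' @param labels Binary labels.
#' @param alpha Stage-1 significance level.
#' @param cutoff Stage-2 Spearman cutoff.
#' @param n_folds,seed Stage-3 CV settings.
#' @return An object of class \code{selection_result}: list with
#'   \code{stage1} (data.frame feature/p), \code{stage2} (names),
#'   \code{stage3} (data.frame feature/coefficient), \code{lambda},
#'   \code{seed}.
#' @export
select_features <- function(features, labels, alpha = 0.05, cutoff = 0.9,
                            n_folds = 10L, seed = 1L) {
  features <- as.data.frame(features)
  s1 <- mwu_prefilter(features, labels, alpha)
  if (nrow(s1) == 0) {
    res <- list(stage1 = s1, stage2 = character(0),
                stage3 = data.frame(feature = character(0),
                                    coefficient = numeric(0)),
                lambda = NA_real_, seed = seed)
    class(res) <- "selection_result"
    return(res)
  }
  pri <- stats::setNames(s1$p, s1$feature)
  s2 <- spearman_prune(features[, s1$feature, drop = FALSE], cutoff,
                       priority = pri)
  if (length(s2) < 2) {
    ## lasso path needs >= 2 columns; with fewer the pruned set stands
    s3 <- data.frame(feature = s2,
                     coefficient = rep(NA_real_, length(s2)),
                     stringsAsFactors = FALSE)
    lam <- NA_real_
  } else {
    s3 <- lasso_select(features[, s2, drop = FALSE], labels, n_folds, seed)
    lam <- attr(s3, "lambda")
  }
  res <- list(stage1 = s1, stage2 = s2, stage3 = s3, lambda = lam,
              seed = seed)
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> cascade:", nrow(x$stage1), "->",
      length(x$stage2), "->", nrow(x$stage3), "features",
      if (is.finite(x$lambda)) sprintf("(lambda = %.4g)", x$lambda) else "",
      "\n")
  if (nrow(x$stage3)) {
    print(utils::head(x$stage3[order(-abs(x$stage3$coefficient)), ], 10),
          row.names = FALSE)
  }
  invisible(x)
}
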