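#' Fit an extremely randomized trees classifier
#'
#' An Extra Trees ensemble: each split draws one random threshold per
#' candidate feature and no bootstrap resampling is used (every tree sees
#' the full sample). Produces class-probability scores; fully reproducible
#' under the seed.
#'
#' @param features Subjects x features table (numeric).
#' @param labels Binary labels.
#' @param num_trees Number of trees (default 500).
#' @param mtry Candidate features per split; default \code{floor(sqrt(p))}.
#' @param min_node_size Minimal node size to split at (default 10, the
#'   usual probability-forest setting; 1 gives fully memorizing trees).
#' @param seed Integer seed.
#' @return An object of class \code{extratrees_model} with a
#'   \code{predict} method returning positive-class probabilities.
#' @export
fit_extratrees <- function(features, labels, num_trees = 500L, mtry = NULL,
                           min_node_size = 10L, seed = 1L) {
  x <- as.data.frame(features)
  stop_if(ncol(x) == 0, "empty feature set")
  y <- factor(as.integer(as.logical(labels)), levels = c(0, 1))
  stop_if(length(unique(y)) < 2, "labels contain a single class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(x = x, y = y, probability = TRUE,
                        num.trees = num_trees, mtry = mtry,
                        min.node.size = min_node_size,
                        splitrule = "extratrees", num.random.splits = 1L,
                        replace = FALSE, sample.fraction = 1,
                        seed = as.integer(seed), num.threads = 1L)
  structure(list(fit = fit, feature_names = colnames(x)),
            class = "extratrees_model")
}

#' @export
predict.extratrees_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  pr <- stats::predict(object$fit, data = nd, num.threads = 1L)$predictions
  as.numeric(pr[, "1"])
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney formulation with midrank tie correction: equals the
#' proportion of (positive, negative) pairs ranked concordantly, ties
#' counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  stop_if(!any(y) || all(y), "labels contain a single class")
  r <- rank(scores)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

## Youden-optimal probability cutoff (max sensitivity + specificity - 1);
## ties resolved toward the smallest cutoff.
youden_threshold <- function(probabilities, labels) {
  y <- as.logical(labels)
  cand <- sort(unique(probabilities))
  if (length(cand) > 1) {
    cuts <- (cand[-1] + cand[-length(cand)]) / 2
  } else cuts <- cand
  j <- vapply(cuts, function(t) {
    mean(probabilities[y] > t) + mean(probabilities[!y] <= t) - 1
  }, numeric(1))
  cuts[which.max(j)]
}

#' Evaluate probabilistic predictions of a binary endpoint
#'
#' AUC by the rank (Mann-Whitney) formulation with a stratified bootstrap
#' percentile CI; accuracy, sensitivity and specificity at a probability
#' cutoff with Clopper-Pearson exact binomial CIs; 10-bin quantile
#' calibration; decision-curve net benefit.
#'
#' @param probabilities Predicted positive-class probabilities in [0, 1].
#' @param labels Binary labels (both classes present).
#' @param prob_threshold Operating cutoff; \code{NULL} selects the
#'   Youden-optimal cutoff on these data (freeze a training cutoff when
#'   evaluating a test set).
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @param model_id,cohort Labels stored in the report.
#' @return An object of class \code{model_report}.
#' @export
evaluate <- function(probabilities, labels, prob_threshold = NULL,
                     n_boot = 2000L, seed = 1L, conf = 0.95,
                     model_id = "model", cohort = "cohort") {
  p <- as.numeric(probabilities)
  stop_if(any(!is.finite(p)) || any(p < 0 | p > 1),
          "probabilities must lie in [0, 1]")
  y <- as.logical(labels)
  stop_if(!any(y) || all(y), "labels contain a single class")
  auc <- auc_rank(p, y)
  ## stratified bootstrap: resample positives and negatives separately
  set.seed(as.integer(seed))
  pos <- which(y); neg <- which(!y)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- c(pos[sample.int(length(pos), replace = TRUE)],
           neg[sample.int(length(neg), replace = TRUE)])
    auc_rank(p[i], y[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  auc_ci <- stats::quantile(boot, c(a, 1 - a), names = FALSE)

  if (is.null(prob_threshold)) prob_threshold <- youden_threshold(p, y)
  pred_pos <- p > prob_threshold
  tp <- sum(pred_pos & y); tn <- sum(!pred_pos & !y)
  fp <- sum(pred_pos & !y); fn <- sum(!pred_pos & y)
  n <- length(y)
  prop_ci <- function(x, m) clopper_pearson(x, m, conf)
  metrics <- data.frame(
    metric = c("accuracy", "sensitivity", "specificity"),
    estimate = c((tp + tn) / n, tp / (tp + fn), tn / (tn + fp)),
    lower = c(prop_ci(tp + tn, n)[1], prop_ci(tp, tp + fn)[1],
              prop_ci(tn, tn + fp)[1]),
    upper = c(prop_ci(tp + tn, n)[2], prop_ci(tp, tp + fn)[2],
              prop_ci(tn, tn + fp)[2]))

  ## 10-bin quantile calibration (degenerate/constant scores collapse to
  ## fewer bins)
  br <- unique(stats::quantile(p, seq(0, 1, 0.1)))
  if (length(br) < 2) br <- c(br - 1e-9, br + 1e-9)
  bins <- cut(p, breaks = br, include.lowest = TRUE)
  calib <- data.frame(
    bin = levels(bins),
    mean_predicted = as.numeric(tapply(p, bins, mean)),
    observed_rate = as.numeric(tapply(as.numeric(y), bins, mean)),
    n = as.integer(table(bins)))

  nb <- decision_curve(p, y)
  structure(list(model_id = model_id, cohort = cohort,
                 auc = auc, auc_ci = auc_ci,
                 prob_threshold = prob_threshold,
                 metrics = metrics, calibration = calib,
                 net_benefit = nb, n = n, n_pos = sum(y)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s / %s (n = %d, %d positive)\n",
              x$model_id, x$cohort, x$n, x$n_pos))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2]))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.1f%% (95%% CI %.1f-%.1f%%)\n", m$metric[i],
                100 * m$estimate[i], 100 * m$lower[i], 100 * m$upper[i]))
  }
  cat(sprintf("  operating cutoff %.3f\n", x$prob_threshold))
  invisible(x)
}

#' Decision-curve analysis (net benefit)
#'
#' Net benefit of treating per model prediction at threshold probability
#' pt: \code{NB = TP/N - FP/N * pt/(1-pt)}, with TP/FP at cutoff pt;
#' treat-all has \code{NB = prevalence - (1-prevalence) * pt/(1-pt)};
#' treat-none is 0.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary labels.
#' @param thresholds Threshold probabilities in (0, 1).
#' @return data.frame with columns \code{threshold}, \code{nb_model},
#'   \code{nb_all}, \code{nb_none}.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  stop_if(any(thresholds <= 0 | thresholds >= 1),
          "thresholds must lie strictly inside (0, 1)")
  y <- as.logical(labels)
  n <- length(y)
  prev <- mean(y)
  rows <- lapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & y) / n
    fp <- sum(pred & !y) / n
    w <- pt / (1 - pt)
    data.frame(threshold = pt, nb_model = tp - fp * w,
               nb_all = prev - (1 - prev) * w, nb_none = 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clinical logistic model with univariate screening
#'
#' Fits a univariate logistic regression of the endpoint on each covariate
#' (Wald odds ratio, 95% CI, p) and builds a multivariable logistic model
#' from the covariates with univariate p below \code{alpha}. Covariates
#' showing complete separation are flagged and excluded with a warning. If
#' no covariate passes the screen, the model is intercept-only (predicts
#' the prevalence).
#'
#' @param covariates data.frame of numeric or binary-encodable covariates.
#' @param labels Binary endpoint.
#' @param alpha Univariate screening level.
#' @return An object of class \code{clinical_model}: list with
#'   \code{univariate} (OR table), \code{fit} (glm), \code{selected}.
#'   Its \code{predict} method returns probabilities.
#' @export
clinical_model <- function(covariates, labels, alpha = 0.05) {
  y <- as.integer(as.logical(labels))
  stop_if(length(unique(y)) < 2, "labels contain a single class")
  x <- as.data.frame(covariates)
  ## encode characters/factors as 0/1 dummies (second sorted level = 1);
  ## remember the coding so predict() reuses it
  coding <- list()
  for (v in names(x)) {
    col <- x[[v]]
    if (!is.numeric(col)) {
      f <- factor(col)
      stop_if(nlevels(f) > 2, "only binary categorical covariates supported")
      coding[[v]] <- levels(f)[nlevels(f)]
      x[[v]] <- as.numeric(as.character(col) == coding[[v]])
    }
  }
  uni <- lapply(names(x), function(v) {
    d <- data.frame(y = y, x = x[[v]])
    fit <- suppressWarnings(stats::glm(y ~ x, data = d, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2 || !is.finite(co[2, 2]) || abs(co[2, 1]) > 15) {
      return(data.frame(covariate = v, or = NA_real_, lower = NA_real_,
                        upper = NA_real_, p = NA_real_, separated = TRUE))
    }
    est <- co[2, 1]; se <- co[2, 2]
    data.frame(covariate = v, or = exp(est),
               lower = exp(est - stats::qnorm(0.975) * se),
               upper = exp(est + stats::qnorm(0.975) * se),
               p = co[2, 4], separated = FALSE)
  })
  uni <- do.call(rbind, uni)
  if (any(uni$separated))
    warning("covariates excluded for complete separation: ",
            paste(uni$covariate[uni$separated], collapse = ", "))
  selected <- uni$covariate[!uni$separated & !is.na(uni$p) & uni$p < alpha]
  d <- cbind(data.frame(y = y), x)
  fml <- if (length(selected))
    stats::as.formula(paste("y ~", paste(selected, collapse = " + ")))
  else stats::as.formula("y ~ 1")
  fit <- suppressWarnings(stats::glm(fml, data = d, family = stats::binomial()))
  structure(list(univariate = uni, fit = fit, selected = selected,
                 covariate_names = names(x), coding = coding),
            class = "clinical_model")
}

#' @export
predict.clinical_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  for (v in names(object$coding)) {
    if (v %in% names(nd))
      nd[[v]] <- as.numeric(as.character(nd[[v]]) == object$coding[[v]])
  }
  as.numeric(stats::predict(object$fit, newdata = nd, type = "response"))
}

#' @export
print.clinical_model <- function(x, ...) {
  cat("<clinical_model> univariate screen:\n")
  u <- x$univariate
  u$or <- signif(u$or, 3); u$lower <- signif(u$lower, 3)
  u$upper <- signif(u$upper, 3); u$p <- signif(u$p, 3)
  print(u, row.names = FALSE)
  cat("multivariable model covariates:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none; intercept only)", "\n")
  invisible(x)
}
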