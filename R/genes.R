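# Expression arm: batch adjustment, moderated-t differential expression,
# glycolysis-list intersection and target-gene correlation.

#' Empirical-Bayes location-scale batch adjustment
#'
#' Removes additive and multiplicative per-gene batch effects from a
#' log-expression matrix, preserving the group contrast via a group
#' covariate in the standardization design. Per gene, the data are
#' standardized against the batch-weighted grand mean and pooled variance;
#' per-batch location (gamma) and scale (delta^2) effects are then
#' estimated and, with \code{eb = TRUE}, shrunk toward their across-gene
#' means by parametric empirical Bayes (normal prior on gamma,
#' inverse-gamma prior on delta^2, hyperparameters by method of moments,
#' solved by the standard fixed-point iteration) before being removed.
#' \code{eb = FALSE} removes the raw per-gene batch effects exactly.
#'
#' @param expr Numeric matrix, genes x samples (log scale).
#' @param batch Per-sample batch labels (>= 2 batches, >= 2 samples each).
#' @param group Optional per-sample group labels to protect (e.g. PD-L1
#'   high/low).
#' @param eb Apply empirical-Bayes shrinkage of the batch effects
#'   (default \code{TRUE}).
#' @return The adjusted matrix (same dimensions).
#' @export
batch_adjust <- function(expr, batch, group = NULL, eb = TRUE) {
  expr <- as.matrix(expr)
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("single batch: returning input unchanged")
    return(expr)
  }
  stop_if(any(table(batch) < 2), "each batch needs at least 2 samples")
  n <- ncol(expr)
  batch_design <- stats::model.matrix(~ -1 + batch)
  design <- batch_design
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) > 1)
      design <- cbind(batch_design,
                      stats::model.matrix(~group)[, -1, drop = FALSE])
  }
  n_batches <- nlevels(batch)
  n_per <- as.numeric(table(batch))

  ## gene-wise OLS for batch means (+ protected covariates)
  B_hat <- solve(crossprod(design), t(design) %*% t(expr))
  grand_mean <- crossprod(n_per / n, B_hat[seq_len(n_batches), , drop = FALSE])
  var_pooled <- rowMeans((expr - t(design %*% B_hat))^2)
  stop_if(any(var_pooled == 0), "gene with zero residual variance")

  stand_mean <- t(matrix(grand_mean, n, nrow(expr), byrow = FALSE))
  stand_mean <- matrix(grand_mean, nrow(expr), n)
  if (ncol(design) > n_batches) {
    extra <- design[, -(seq_len(n_batches)), drop = FALSE]
    stand_mean <- stand_mean +
      t(extra %*% B_hat[-(seq_len(n_batches)), , drop = FALSE])
  }
  Z <- (expr - stand_mean) / sqrt(var_pooled)

  ## per-batch location/scale on the standardized scale
  gamma_hat <- t(solve(crossprod(batch_design), t(batch_design) %*% t(Z)))
  delta_hat <- sapply(levels(batch), function(b) {
    zb <- Z[, batch == b, drop = FALSE]
    apply(zb, 1, function(r) mean((r - mean(r))^2) * length(r) / (length(r) - 1))
  })
  gamma_star <- gamma_hat
  delta_star <- delta_hat

  if (eb) {
    for (bi in seq_len(n_batches)) {
      g <- gamma_hat[, bi]
      d <- delta_hat[, bi]
      g_bar <- mean(g)
      t2 <- stats::var(g)
      m <- mean(d); s2 <- stats::var(d)
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      nb <- n_per[bi]
      zb <- Z[, batch == levels(batch)[bi], drop = FALSE]
      g_new <- g; d_new <- d
      change <- 1
      iter <- 0
      while (change > 1e-4 && iter < 200) {
        g_old <- g_new; d_old <- d_new
        g_new <- (t2 * nb * g + d_new * g_bar) / (t2 * nb + d_new)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                      abs(d_new - d_old) / abs(d_old + 1e-12))
        iter <- iter + 1
      }
      gamma_star[, bi] <- g_new
      delta_star[, bi] <- d_new
    }
  }

  out <- Z
  for (bi in seq_len(n_batches)) {
    sel <- batch == levels(batch)[bi]
    out[, sel] <- (Z[, sel, drop = FALSE] - gamma_star[, bi]) /
      sqrt(delta_star[, bi])
  }
  out * sqrt(var_pooled) + stand_mean
}

## Newton solve of trigamma(x) = y (vectorized), for the EB prior df.
trigamma_inverse <- function(y) {
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    yi <- y[i]
    if (!is.finite(yi) || yi <= 0) { out[i] <- Inf; next }
    if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
    if (yi < 1e-6) { out[i] <- 1 / yi; next }
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    out[i] <- x
  }
  out
}

#' Moderated-t differential expression between two groups
#'
#' Per-gene two-sample comparison with empirical-Bayes variance
#' shrinkage: gene-wise pooled variances are assumed to follow a scaled F
#' distribution around a prior variance s0^2 with prior degrees of freedom
#' d0; (d0, s0^2) are estimated by method of moments on the log variances
#' (trigamma inversion), each gene's variance is shrunk to
#' \code{(d0 s0^2 + d s^2) / (d0 + d)}, and the t statistic is referred to
#' a t distribution with d + d0 degrees of freedom. P-values are adjusted
#' by Benjamini-Hochberg; a direction is assigned only below the FDR
#' threshold.
#'
#' @param expr Genes x samples log-expression matrix.
#' @param group Two-level per-sample labels; the contrast is the non-
#'   reference level minus the reference level.
#' @param ref Reference group level; defaults to the first sorted level
#'   (so with labels "PD-L1-high"/"PD-L1-low" pass \code{ref =
#'   "PD-L1-low"} to report effects as high minus low).
#' @param fdr_threshold FDR significance level (default 0.05).
#' @param prior_df Override the estimated prior degrees of freedom; 0
#'   yields the ordinary pooled two-sample t test, \code{Inf} fixes all
#'   variances at s0^2.
#' @return An object of class \code{de_result}: data.frame with columns
#'   \code{gene}, \code{mean_diff}, \code{t}, \code{p}, \code{fdr},
#'   \code{direction}; shrinkage hyperparameters in attributes
#'   \code{"prior_df"} and \code{"prior_var"}.
#' @export
differential_expression <- function(expr, group, fdr_threshold = 0.05,
                                    ref = NULL) {
  expr <- as.matrix(expr)
  group <- relevel_group(group, ref)
  stop_if(any(table(group) < 2), "need >= 2 samples per group")
  de_core(expr, group, fdr_threshold, prior_df = NULL)
}

relevel_group <- function(group, ref) {
  group <- factor(group)
  stop_if(nlevels(group) != 2, "group must have exactly two levels")
  if (!is.null(ref)) {
    stop_if(!ref %in% levels(group), "ref is not a group level")
    group <- stats::relevel(group, ref)
  }
  group
}

de_core <- function(expr, group, fdr_threshold, prior_df = NULL) {
  g2 <- group == levels(group)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(expr[, !g2, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  diff <- m2 - m1
  ss1 <- rowSums((expr[, !g2, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, g2, drop = FALSE] - m2)^2)
  df_resid <- n1 + n2 - 2
  stop_if(df_resid <= 0, "zero residual degrees of freedom")
  s2 <- (ss1 + ss2) / df_resid

  if (is.null(prior_df)) {
    hp <- squeeze_hyperparameters(s2, df_resid)
    d0 <- hp$prior_df; s02 <- hp$prior_var
  } else if (prior_df == 0) {
    d0 <- 0; s02 <- mean(s2)
  } else if (is.infinite(prior_df)) {
    d0 <- Inf
    s02 <- exp(mean(log(s2)) - digamma(df_resid / 2) + log(df_resid / 2))
  } else {
    d0 <- prior_df
    s02 <- exp(mean(log(s2)) - digamma(df_resid / 2) + log(df_resid / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
    else (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- diff / se
  df_total <- if (is.infinite(d0)) Inf else df_resid + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  fdr <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(fdr < fdr_threshold,
                      ifelse(diff > 0, "up", "down"), "ns")
  out <- data.frame(gene = rownames(expr), mean_diff = diff, t = tstat,
                    p = p, fdr = fdr, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  class(out) <- c("de_result", class(out))
  out
}

#' @rdname differential_expression
#' @export
differential_expression_fixed_prior <- function(expr, group,
                                                fdr_threshold = 0.05,
                                                prior_df = 0, ref = NULL) {
  expr <- as.matrix(expr)
  group <- relevel_group(group, ref)
  de_core(expr, group, fdr_threshold, prior_df = prior_df)
}

## Method-of-moments fit of the scaled-F model on log variances, as in the
## standard EB variance-shrinkage construction: with e = log(s^2) adjusted
## for the digamma bias of chi^2 variances, var(e) - trigamma(d/2) =
## trigamma(d0/2).
squeeze_hyperparameters <- function(s2, df_resid) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  e_bar <- mean(e)
  v <- mean((e - e_bar)^2) * length(e) / max(1, length(e) - 1)
  rhs <- v - trigamma(df_resid / 2)
  if (rhs <= 0) {
    d0 <- Inf
    s02 <- exp(e_bar)
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(prior_df = d0, prior_var = s02)
}

#' Intersect DE genes with a glycolysis list and correlate with the PD-L1
#' transcript
#'
#' Computes the set intersection of the significant DE genes with a
#' glycolysis gene list, then the tie-corrected Spearman correlation (and
#' two-sided p) between each intersected gene's expression and the target
#' (PD-L1) transcript across all samples. An empty intersection returns an
#' empty report.
#'
#' @param de A \code{de_result}.
#' @param glycolysis_list Character vector of gene ids.
#' @param expr Genes x samples matrix (post-adjustment scale recommended).
#' @param target_gene_id Row name of the PD-L1 transcript stand-in.
#' @return An object of class \code{glyco_report}: list with
#'   \code{de_genes}, \code{intersected}, \code{correlations} (data.frame
#'   gene/rho/p).
#' @export
intersect_and_correlate <- function(de, glycolysis_list, expr,
                                    target_gene_id) {
  expr <- as.matrix(expr)
  stop_if(!target_gene_id %in% rownames(expr),
          "target gene not present in the expression matrix")
  de_genes <- de$gene[de$direction != "ns"]
  inter <- intersect(de_genes, glycolysis_list)
  target <- as.numeric(expr[target_gene_id, ])
  cors <- if (length(inter)) {
    do.call(rbind, lapply(inter, function(g) {
      ct <- suppressWarnings(
        stats::cor.test(as.numeric(expr[g, ]), target,
                        method = "spearman", exact = FALSE))
      data.frame(gene = g, rho = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(gene = character(0), rho = numeric(0), p = numeric(0))
  structure(list(de_genes = de_genes, intersected = inter,
                 correlations = cors),
            class = "glyco_report")
}

#' @export
print.glyco_report <- function(x, ...) {
  cat("<glyco_report>", length(x$de_genes), "DE genes,",
      length(x$intersected), "glycolysis-related\n")
  if (nrow(x$correlations)) {
    top <- x$correlations[order(-abs(x$correlations$rho)), ]
    print(utils::head(top, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Batch-mixing score (mean silhouette by batch label)
#'
#' Quantifies residual batch structure: the mean silhouette width of
#' samples under the batch labelling, computed on Euclidean distances over
#' the most variable genes. Values near 0 (or below) indicate well-mixed
#' batches; effective batch adjustment shrinks this score.
#'
#' @param expr Genes x samples matrix.
#' @param batch Per-sample batch labels.
#' @param n_genes Number of top-variance genes used (default 500).
#' @return Mean silhouette width (scalar).
#' @export
batch_silhouette <- function(expr, batch, n_genes = 500L) {
  expr <- as.matrix(expr)
  batch <- factor(batch)
  stop_if(nlevels(batch) < 2, "need >= 2 batches")
  v <- apply(expr, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_genes, nrow(expr)))]
  d <- as.matrix(stats::dist(t(expr[top, , drop = FALSE])))
  n <- ncol(expr)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- batch == batch[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(levels(batch), as.character(batch[i])),
                    function(bl) mean(d[i, batch == bl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
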