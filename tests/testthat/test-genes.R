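test_that("single-batch input is returned unchanged with a warning", {
  m <- matrix(rnorm(50), 10, 5)
  expect_warning(out <- batch_adjust(m, rep("A", 5)), "single batch")
  expect_identical(out, m)
})

test_that("exact mode removes a pure per-gene location shift completely", {
  set.seed(91)
  g <- 40; n <- 20
  base <- matrix(rnorm(g * n), g, n)
  batch <- rep(c("A", "B"), each = n / 2)
  delta <- rnorm(g, 1.5, 0.2)
  shifted <- base
  shifted[, batch == "B"] <- shifted[, batch == "B"] + delta
  adj <- batch_adjust(shifted, batch, eb = FALSE)
  d_post <- rowMeans(adj[, batch == "B"]) - rowMeans(adj[, batch == "A"])
  expect_lt(max(abs(d_post)), 1e-8)
})

test_that("EB adjustment matches the reference ComBat implementation", {
  ex <- generate_expression(n_genes = 300, n_samples = 40,
                            n_glycolysis = 80,
                            de_spec = list(n_up = 6, n_down = 2,
                                           effect = 1.5), seed = 12)
  mine <- batch_adjust(ex$log_expression, ex$batch, ex$group, eb = TRUE)
  mod <- stats::model.matrix(~ factor(ex$group))
  ref <- suppressMessages(sva::ComBat(ex$log_expression, batch = ex$batch,
                                      mod = mod, par.prior = TRUE))
  ## both iterate the same EB fixed point to a 1e-4 stopping rule, so they
  ## agree to the convergence scale, not machine precision
  expect_lt(max(abs(mine - ref)), 1e-3)
  expect_gt(stats::cor(as.numeric(mine), as.numeric(ref)), 1 - 1e-10)
})

test_that("adjustment centres planted batch differences and preserves group contrasts", {
  shifts <- sapply(1:10, function(r) {
    ex <- generate_expression(n_genes = 400, n_samples = 100,
                              batch_shift = c(1.5, 2.0),
                              n_glycolysis = 100,
                              de_spec = list(n_up = 10, n_down = 0,
                                             effect = 2),
                              seed = 4000 + r)
    adj <- batch_adjust(ex$log_expression, ex$batch, ex$group)
    d <- rowMeans(adj[, ex$batch == "B"]) - rowMeans(adj[, ex$batch == "A"])
    hi <- ex$group == "PD-L1-high"
    contrast <- rowMeans(adj[, hi]) - rowMeans(adj[, !hi])
    c(batch = mean(d),
      contrast_shift = mean(contrast[names(ex$planted_de)]) - 2)
  })
  expect_lt(abs(mean(shifts["batch", ])), 0.05)
  expect_lt(abs(mean(shifts["contrast_shift", ])), 0.05)
})

test_that("batch silhouette shrinks after adjustment", {
  ex <- generate_expression(n_genes = 500, n_samples = 60,
                            batch_shift = c(1.2, 1.5),
                            n_glycolysis = 100,
                            de_spec = list(n_up = 5, n_down = 0,
                                           effect = 1.5), seed = 23)
  s_before <- batch_silhouette(ex$log_expression, ex$batch)
  s_after <- batch_silhouette(batch_adjust(ex$log_expression, ex$batch,
                                           ex$group), ex$batch)
  expect_lt(s_after, s_before)
  expect_lt(s_after, 0.05)
})

test_that("zero prior df reduces the moderated t to the ordinary pooled t", {
  set.seed(33)
  m <- matrix(rnorm(200 * 16), 200, 16,
              dimnames = list(sprintf("g%03d", 1:200), NULL))
  grp <- rep(c("lo", "hi"), each = 8)
  de0 <- differential_expression_fixed_prior(m, grp, prior_df = 0)
  t_ref <- apply(m, 1, function(r) {
    stats::t.test(r[grp == "lo"], r[grp == "hi"],
                  var.equal = TRUE)$statistic
  })
  expect_equal(abs(de0$t), unname(abs(t_ref)), tolerance = 1e-10)
  ## infinite prior df pools all variances
  deInf <- differential_expression_fixed_prior(m, grp, prior_df = Inf)
  se_implied <- abs(de0$mean_diff / deInf$t)
  expect_lt(stats::sd(se_implied), 1e-10)
  ## intermediate prior df interpolates each gene's posterior variance
  ## between its own variance and that df's prior variance
  de8 <- differential_expression_fixed_prior(m, grp, prior_df = 8)
  scale2 <- 1 / 8 + 1 / 8
  s2 <- (de0$mean_diff / de0$t)^2 / scale2
  s2_8 <- (de8$mean_diff / de8$t)^2 / scale2
  s02 <- attr(de8, "prior_var")
  lo <- pmin(s2, s02) - 1e-10
  hi <- pmax(s2, s02) + 1e-10
  expect_true(all(s2_8 >= lo & s2_8 <= hi))
  ## and sits closer to the prior than the raw variance does
  expect_true(all(abs(s2_8 - s02) <= abs(s2 - s02) + 1e-10))
})

test_that("moderated t agrees with the reference limma implementation", {
  ex <- generate_expression(n_genes = 400, n_samples = 50,
                            batch_shift = c(0, 1),
                            n_glycolysis = 100,
                            de_spec = list(n_up = 8, n_down = 2,
                                           effect = 1.5), seed = 9)
  de <- differential_expression(ex$log_expression, ex$group)
  design <- stats::model.matrix(~ factor(ex$group))
  fit <- limma::eBayes(limma::lmFit(ex$log_expression, design))
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(de, "prior_var"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(abs(de$t), unname(abs(fit$t[, 2])), tolerance = 1e-10)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("BH adjustment matches the hand example and a brute-force step-up", {
  p <- c(0.005, 0.011, 0.02, 0.04)
  expect_equal(stats::p.adjust(p, "BH"),
               c(0.02, 0.022, 0.02 * 4 / 3, 0.04), tolerance = 1e-12)
  set.seed(55)
  for (r in 1:50) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(pv, "BH"), brute_bh(pv),
                 tolerance = 1e-12)
  }
})

test_that("planted DE genes are recovered with controlled false positives", {
  ex <- generate_expression(n_genes = 2000, n_samples = 100,
                            batch_shift = c(0, 1),
                            n_glycolysis = 753, glyco_de_overlap = 4,
                            de_spec = list(n_up = 10, n_down = 10,
                                           effect = 2.0),
                            noise_sd = 0.5, seed = 77)
  de <- differential_expression(ex$log_expression, ex$group,
                                ref = "PD-L1-low")
  called <- de$gene[de$direction != "ns"]
  tp <- length(intersect(called, names(ex$planted_de)))
  fp <- length(setdiff(called, names(ex$planted_de)))
  expect_gte(tp, 18)
  expect_lte(fp, 5)
  ## every called planted gene carries the planted sign
  called_planted <- intersect(called, names(ex$planted_de))
  dir_called <- de$direction[match(called_planted, de$gene)]
  expect_true(all((dir_called == "up") ==
                    (ex$planted_de[called_planted] > 0)))
})

test_that("intersection and Spearman correlation behave per contract", {
  ex <- generate_expression(n_genes = 300, n_samples = 60,
                            batch_shift = c(0, 1),
                            n_glycolysis = 80, glyco_de_overlap = 3,
                            de_spec = list(n_up = 6, n_down = 2,
                                           effect = 2), seed = 31)
  de <- differential_expression(ex$log_expression, ex$group)
  gr <- intersect_and_correlate(de, ex$glycolysis_list,
                                ex$log_expression, ex$target_gene_id)
  expect_true(all(gr$intersected %in% gr$de_genes))
  expect_true(all(gr$intersected %in% ex$glycolysis_list))
  expect_true(all(abs(gr$correlations$rho) <= 1))

  ## disjoint lists: empty report, no error
  gr0 <- intersect_and_correlate(de, c("ZZZ1", "ZZZ2"),
                                 ex$log_expression, ex$target_gene_id)
  expect_length(gr0$intersected, 0)

  ## monotone transform of the target has rho exactly 1
  m <- ex$log_expression
  m["G00002", ] <- exp(m[ex$target_gene_id, ] / 3)
  de2 <- de
  de2$direction[de2$gene == "G00002"] <- "up"
  gr2 <- intersect_and_correlate(de2, c("G00002"), m, ex$target_gene_id)
  expect_equal(gr2$correlations$rho, 1)

  ## tie-corrected rho equals ranked Pearson with midranks
  x <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 9, 9)
  rho_mid <- stats::cor(rank(x), rank(y))
  m2 <- rbind(a = x, b = y)
  de3 <- data.frame(gene = "b", mean_diff = 1, t = 1, p = 0.01,
                    fdr = 0.01, direction = "up")
  gr3 <- intersect_and_correlate(de3, "b", m2, "a")
  expect_equal(gr3$correlations$rho, rho_mid, tolerance = 1e-12)
})
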