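test_that("cohort generation is deterministic under the seed and invariant to cohort size", {
  cfg <- small_phantom(n_subjects = 3, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ## subject-level substreams: subject 2 identical in a larger cohort
  cfg5 <- small_phantom(n_subjects = 5, seed = 11)
  c5 <- generate_cohort(cfg5)
  expect_identical(a[[2]], c5[[2]])
})

test_that("phantom volumes respect the shared-grid and habitat invariants", {
  cfg <- small_phantom(n_subjects = 3, seed = 4)
  for (s in generate_cohort(cfg)) {
    expect_identical(dim(s$pet), dim(s$ct))
    expect_identical(dim(s$pet), dim(s$voi_mask))
    expect_gt(sum(s$voi_mask), 0)
    ## habitat labels defined exactly on the VOI
    expect_true(all(s$true_habitat[s$voi_mask == 1] %in% 1:4))
    expect_true(all(s$true_habitat[s$voi_mask == 0] == 0))
    ## rasterized fractions track the latent fraction vector
    realized <- tabulate(s$true_habitat[s$voi_mask == 1], 4) / sum(s$voi_mask)
    expect_lt(max(abs(realized - s$true_fractions)), 0.02)
  }
})

test_that("null logistic model gives prevalence 0.5 within Monte-Carlo error", {
  cfg <- phantom_config(n_subjects = 2000, beta0 = 0, beta1 = 0,
                        or_histology = 1, or_nse = 1, seed = 21)
  co <- generate_cohort(cfg, rasterize = FALSE)
  prev <- mean(vapply(co, function(s) s$pdl1_positive, logical(1)))
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(prev - 0.5), 3 * se)
})

test_that("non-separable intensity modes are rejected at configuration", {
  expect_error(phantom_config(pet_means = c(8, 2)), "exceed")
  expect_error(phantom_config(pet_means = c(2, 3), pet_sd = 0.4),
               "separable")
  expect_error(phantom_config(n_subjects = 1), "n_subjects")
})

test_that("habitat-1 fraction sampler matches its configured mean and the planted slope is recoverable", {
  cfg <- phantom_config(n_subjects = 1500, seed = 33)
  co <- generate_cohort(cfg, rasterize = FALSE)
  f1 <- vapply(co, function(s) s$true_fractions[1], numeric(1))
  ## symmetric Dirichlet: component mean 1/4
  expect_lt(abs(mean(f1) - 0.25), 3 * stats::sd(f1) / sqrt(length(f1)))
  ## Wald CI for the planted slope covers the truth in most replicates
  hits <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cfg_r <- phantom_config(n_subjects = 1000, beta1 = log(8.84),
                            beta0 = -0.35, or_histology = 1, or_nse = 1,
                            seed = 400 + r)
    tab <- cohort_table(generate_cohort(cfg_r, rasterize = FALSE))
    fit <- stats::glm(pdl1_positive ~ f1, data = tab,
                      family = stats::binomial())
    est <- summary(fit)$coefficients["f1", ]
    lo <- est[1] - 1.96 * est[2]
    hi <- est[1] + 1.96 * est[2]
    if (lo <= log(8.84) && log(8.84) <= hi) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * n_rep) - 1)
})

test_that("expression generator plants group effects, batches and list sizes as configured", {
  ## null generator: between-group mean differences centred at 0
  ex0 <- generate_expression(n_genes = 400, n_samples = 40,
                             batch_shift = c(0, 1),
                             de_spec = list(n_up = 0, n_down = 0, effect = 0),
                             n_glycolysis = 100, glyco_de_overlap = 0,
                             seed = 5)
  hi <- ex0$group == "PD-L1-high"
  d <- rowMeans(ex0$log_expression[, hi]) - rowMeans(ex0$log_expression[, !hi])
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)) + 0.02)
  expect_length(ex0$planted_de, 0)

  ## planted genes have the largest group differences
  ex <- generate_expression(n_genes = 500, n_samples = 100,
                            batch_shift = c(0, 1),
                            de_spec = list(n_up = 10, n_down = 10,
                                           effect = 2),
                            n_glycolysis = 100, glyco_de_overlap = 5,
                            noise_sd = 0.5, seed = 6)
  hi <- ex$group == "PD-L1-high"
  d <- abs(rowMeans(ex$log_expression[, hi]) -
             rowMeans(ex$log_expression[, !hi]))
  top20 <- names(sort(d, decreasing = TRUE))[1:20]
  expect_setequal(top20, names(ex$planted_de))

  ## glycolysis list size and overlap contract
  ex753 <- generate_expression(n_genes = 1000, n_samples = 20,
                               n_glycolysis = 753,
                               de_spec = list(n_up = 5, n_down = 0,
                                              effect = 1),
                               glyco_de_overlap = 2, seed = 7)
  expect_length(ex753$glycolysis_list, 753)
  expect_length(intersect(ex753$glycolysis_list, names(ex753$planted_de)), 2)
  expect_true(ex753$target_gene_id %in% ex753$gene_ids)
  expect_error(generate_expression(n_genes = 100, n_samples = 20,
                                   n_glycolysis = 50,
                                   de_spec = list(n_up = 2, n_down = 0,
                                                  effect = 1),
                                   glyco_de_overlap = 10),
               "overlap")
})
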