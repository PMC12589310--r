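test_that("extra trees memorize separable data and are seed-deterministic", {
  set.seed(2)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- data.frame(f1 = rnorm(n, ifelse(y == 1, 10, 0), 0.1),
                  f2 = rnorm(n, ifelse(y == 1, -5, 5), 0.1))
  fit <- fit_extratrees(x, y, min_node_size = 1L, seed = 9)
  expect_equal(auc_rank(predict(fit, x), y), 1.0)
  fit2 <- fit_extratrees(x, y, min_node_size = 1L, seed = 9)
  expect_identical(predict(fit, x), predict(fit2, x))
  expect_error(fit_extratrees(x[, 0], y), "empty")
})

test_that("extra trees held-out AUC is near 0.5 on permuted labels", {
  set.seed(6)
  n <- 200
  x <- as.data.frame(matrix(rnorm(n * 10), n))
  y <- sample(rep(c(0, 1), each = n / 2))
  aucs <- vapply(1:5, function(r) {
    tr <- c(sample(which(y == 1), 50), sample(which(y == 0), 50))
    fit <- fit_extratrees(x[tr, ], y[tr], seed = r)
    auc_rank(predict(fit, x[-tr, ]), y[-tr])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("rank AUC equals the all-pairs concordance oracle", {
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_rank(1:10, c(rep(0, 5), rep(1, 5))), 1.0)
  set.seed(17)
  for (r in 1:30) {
    n <- sample(10:100, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties on purpose
    expect_equal(auc_rank(s, y), brute_auc(s, y), tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson endpoints reproduce the closed forms at x = 0 and x = n", {
  for (n in c(1, 5, 10, 23, 50)) {
    ci0 <- clopper_pearson(0, n)
    expect_equal(ci0[["lower"]], 0)
    expect_equal(ci0[["upper"]], 1 - 0.025^(1 / n), tolerance = 1e-12)
    cin <- clopper_pearson(n, n)
    expect_equal(cin[["upper"]], 1)
    expect_equal(cin[["lower"]], 0.025^(1 / n), tolerance = 1e-12)
  }
  ## interior case against binom.test
  bt <- stats::binom.test(7, 20)$conf.int
  ci <- clopper_pearson(7, 20)
  expect_equal(unname(ci), as.numeric(bt), tolerance = 1e-12)
})

test_that("evaluate produces a coherent report with exact CIs and calibration bins", {
  set.seed(23)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  p <- plogis(2 * y - 1 + rnorm(n))
  rep <- evaluate(p, y, n_boot = 300, seed = 3)
  expect_s3_class(rep, "model_report")
  expect_true(rep$auc >= rep$auc_ci[1] && rep$auc <= rep$auc_ci[2])
  m <- rep$metrics
  expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
  expect_equal(sum(rep$calibration$n), n)
  expect_true(all(rep$net_benefit$nb_none == 0))
  expect_equal(evaluate(sort(runif(30)), c(rep(0, 15), rep(1, 15)),
                        n_boot = 50)$auc, 1.0)
  expect_error(evaluate(rep(0.5, 10), rep(1, 10)), "single class")
  expect_error(evaluate(c(-0.1, 0.5), c(0, 1)), "probabilities")
})

test_that("bootstrap AUC CI covers the generating model's true AUC", {
  ## true AUC of the binormal score model, computed in closed form
  mu <- 1.2
  true_auc <- pnorm(mu / sqrt(2))
  hits <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    set.seed(500 + r)
    n <- 150
    y <- rbinom(n, 1, 0.5)
    s <- rnorm(n, mean = mu * y)
    rep <- evaluate(plogis(s), y, n_boot = 400, seed = r)
    if (rep$auc_ci[1] <= true_auc && true_auc <= rep$auc_ci[2])
      hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("decision curve reproduces the closed-form net benefits", {
  y <- rep(c(1, 0), each = 50)
  p_perfect <- rep(c(0.9, 0.05), each = 50)
  dc <- decision_curve(p_perfect, y, thresholds = 0.25)
  expect_equal(dc$nb_model, 0.5)
  expect_equal(dc$nb_all, 0.5 - 0.5 * (0.25 / 0.75), tolerance = 1e-12)
  expect_equal(dc$nb_all, 1 / 3, tolerance = 1e-12)
  ## pt -> 0+ limit: treat-all net benefit approaches prevalence
  dc0 <- decision_curve(p_perfect, y, thresholds = 1e-6)
  expect_equal(dc0$nb_all, 0.5, tolerance = 1e-5)
  expect_error(decision_curve(p_perfect, y, thresholds = 1), "inside")
})

test_that("clinical model matches closed-form odds ratios and recovers planted effects", {
  ## balanced null 2x2 table: OR 1, p ~ 1
  x <- rep(c(1, 1, 0, 0), each = 10)
  y <- rep(c(1, 0, 1, 0), each = 10)
  cm <- clinical_model(data.frame(exposure = x), y)
  expect_equal(cm$univariate$or, 1, tolerance = 1e-8)
  expect_gt(cm$univariate$p, 0.99)

  ## a=3, b=1, c=1, d=3: logistic OR equals the cross-product ratio 9
  x2 <- c(rep(1, 4), rep(0, 4))
  y2 <- c(1, 1, 1, 0, 1, 0, 0, 0)
  cm2 <- clinical_model(data.frame(exposure = x2), y2)
  expect_equal(cm2$univariate$or, 9, tolerance = 1e-6)

  ## planted OR 1.7 recovery at n = 2000
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    set.seed(700 + r)
    n <- 2000
    x3 <- rbinom(n, 1, 0.5)
    y3 <- rbinom(n, 1, plogis(-0.2 + log(1.7) * x3))
    cm3 <- clinical_model(data.frame(exposure = x3), y3)
    u <- cm3$univariate
    if (u$lower <= 1.7 && 1.7 <= u$upper) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * n_rep) - 1)

  ## separation flagged and excluded
  xs <- c(rep(0, 10), rep(1, 10))
  expect_warning(cs <- clinical_model(data.frame(sep = xs, ok = rnorm(20)),
                                      xs), "separation")
  expect_true(cs$univariate$separated[cs$univariate$covariate == "sep"])
})
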