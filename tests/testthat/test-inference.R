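test_that("range scaling normalises to [0, 1] and flags constants", {
  expect_equal(range_scale(c(2, 4, 6)), c(0, 0.5, 1))
  con <- range_scale(rep(3, 5))
  expect_equal(as.numeric(con), rep(0, 5))
  expect_true(attr(con, "constant"))
  set.seed(2)
  x <- rnorm(40)
  expect_equal(range(range_scale(x)), c(0, 1))
  expect_error(range_scale(numeric(0)), "empty")
})

test_that("the Spearman screen equals brute-force rank-then-Pearson", {
  expect_equal(oracle_spearman(1:8, (1:8)^2), 1)
  expect_equal(oracle_spearman(1:8, -(1:8)), -1)
  st <- synth_memory_study(memory_scenario(n_events = 12), n_years = 4,
                           seed = 31)
  sp <- spearman_screen(st$descriptors, st$diversity)
  expect_equal(nrow(sp), 3 * 6 * 6)
  for (i in sample(nrow(sp), 12)) {
    row <- sp[i, ]
    dw <- st$descriptors[st$descriptors$window == row$window, ]
    expect_equal(row$rho,
                 oracle_spearman(dw[[row$descriptor]],
                                 st$diversity[[row$index]]),
                 tolerance = 1e-12)
  }
  # tied data agree with the average-rank formula
  x <- c(1, 2, 2, 3, 5, 5, 5, 9)
  y <- c(2, 1, 4, 4, 6, 7, 7, 8)
  expect_equal(cor(x, y, method = "spearman"), oracle_spearman(x, y))
})

test_that("a linear signal is recovered at least-squares accuracy", {
  set.seed(51)
  n <- 40
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  names(X) <- c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")
  y <- 1 + 2 * X$sum_fall + rnorm(n, 0, 0.3)
  fit <- fit_flow_gam(y, X, ar1 = FALSE)
  ols <- summary(lm(y ~ sum_fall, data = X))$adj.r.squared
  expect_lt(abs(fit$r2_adj - ols), 0.05)
  # the informative smooth stays effectively linear
  sm <- summary(fit$model)
  edf_fall <- sm$edf[grep("sum_fall", rownames(sm$s.table))]
  expect_lt(edf_fall, 1.5)
})

test_that("a quadratic signal beats every purely linear model in-sample", {
  set.seed(52)
  n <- 50
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  names(X) <- c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")
  y <- (X$rb - 0.3)^2 + rnorm(n, 0, 0.1)
  fit <- fit_flow_gam(y, X, ar1 = FALSE)
  lin_rmse <- vapply(names(X), function(v) {
    m <- lm(stats::reformulate(v, "y"), data = cbind(X, y = y))
    sqrt(mean(residuals(m)^2))
  }, numeric(1))
  expect_lt(fit$rmse, min(lin_rmse))
})

test_that("metrics follow the SSE/SST arithmetic and degenerate limits", {
  set.seed(53)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  names(X) <- c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")
  y <- 0.5 * X$q_mean + rnorm(n, 0, 0.4)
  fit <- fit_flow_gam(y, X, ar1 = FALSE)
  met <- model_metrics(fit)
  sse <- sum((fit$y - fit$fitted)^2)
  sst <- sum((fit$y - mean(fit$y))^2)
  r2 <- 1 - sse / sst
  expect_equal(met$r2, r2, tolerance = 1e-12)
  expect_equal(met$rmse, sqrt(sse / n), tolerance = 1e-12)
  expect_equal(met$r2_adj,
               1 - (1 - r2) * (n - 1) / (n - met$p_eff - 1),
               tolerance = 1e-12)
  expect_lte(met$r2_adj, met$r2)

  # constant response: no explainable variance, near-zero error
  fit0 <- fit_flow_gam(rep(1.7, n), X, ar1 = FALSE)
  expect_lte(fit0$r2_adj, 0)
  expect_lt(fit0$rmse, 1e-6)
})

test_that("beta-family fits keep proportions inside the unit interval", {
  set.seed(54)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  names(X) <- c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")
  y <- plogis(X$sum_fall + rnorm(n, 0, 0.5))
  y[1] <- 1  # boundary value must be squeezed, not fatal
  fit <- fit_flow_gam(y, X, family = "beta", ar1 = FALSE)
  expect_true(all(fit$y > 0 & fit$y < 1))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_true(fit$fallback_event_smooth)
  expect_error(fit_flow_gam(y * 2, X, family = "beta"), "\\[0, 1\\]")
})

test_that("the Shapiro-Wilk diagnostic has its nominal behaviour", {
  flags <- vapply(1:200, function(s) {
    set.seed(s)
    r <- rnorm(20)
    shapiro.test(r)$p.value >= 0.05
  }, logical(1))
  expect_gt(mean(flags), 0.90)  # nominal 95% acceptance for normal draws

  heavy <- vapply(1:100, function(s) {
    set.seed(s)
    r <- exp(rnorm(20, sd = 1.5))
    shapiro.test(r)$p.value >= 0.05
  }, logical(1))
  expect_lt(mean(heavy), 0.5)   # strong lognormal skew is mostly rejected

  set.seed(60)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 6), n))
  names(X) <- c("q_mean", "rb", "n_rise", "sum_rise", "sum_fall", "sum_abs")
  fit <- fit_flow_gam(rnorm(n), X, ar1 = FALSE)
  sw <- residual_normality(fit)
  expect_gte(sw$p, 0)
  expect_lte(sw$p, 1)
  expect_identical(sw$normal, sw$p >= 0.05)
})
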