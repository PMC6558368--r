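test_that("perfectly linear data give R2 = 1 and standardized beta 1", {
  d <- tibble::tibble(x = 1:20, y = 2 * (1:20))
  fit <- fit_lm(d, "y", "x")
  suppressWarnings({  # lm warns about the (intentionally) perfect fit
    g <- glance(fit)
    expect_equal(g$r2, 1)
    expect_equal(tidy(fit)$beta_std, 1, tolerance = 1e-10)
  })
})

test_that("fit_lm matches the closed-form normal equations on a hand fixture", {
  d <- tibble::tibble(x1 = c(1, 2, 3, 4, 5),
                      x2 = c(2, 1, 4, 3, 6),
                      y = c(3, 5, 7, 10, 12))
  fit <- fit_lm(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(coef(fit$fit_raw)), as.numeric(beta), tolerance = 1e-10)
  rss <- sum((d$y - X %*% beta)^2)
  expect_equal(glance(fit)$r2, 1 - rss / sum((d$y - mean(d$y))^2),
               tolerance = 1e-10)
  # standardized betas equal raw betas rescaled by sd ratios
  td <- tidy(fit)
  expect_equal(td$beta_std,
               as.numeric(beta[2:3]) * c(sd(d$x1), sd(d$x2)) / sd(d$y),
               tolerance = 1e-10)
  # AIC under the Gaussian ML convention with constants
  n <- nrow(d)
  expect_equal(glance(fit)$aic,
               n * log(2 * pi * rss / n) + n + 2 * 4, tolerance = 1e-8)
})

test_that("row order does not affect the fit", {
  set.seed(2)
  d <- tibble::tibble(x = rnorm(30), z = rnorm(30),
                      y = 1 + 0.5 * x + rnorm(30))
  f1 <- fit_lm(d, "y", c("x", "z"))
  f2 <- fit_lm(d[sample(30), ], "y", c("x", "z"))
  expect_equal(tidy(f1), tidy(f2), tolerance = 1e-12)
  expect_equal(glance(f1), glance(f2), tolerance = 1e-12)
})

test_that("degenerate designs are refused", {
  d <- tibble::tibble(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_lm(d, "y", c("x", "x2")),
               class = "minimuse_rank_deficient")
  expect_error(fit_lm(d[1:2, ], "y", "x"), "complete cases")
  expect_error(fit_lm(d, "y", "missing_col"), "missing columns")
})

test_that("backward elimination drops irrelevant predictors", {
  set.seed(101)
  n <- 200
  d <- tibble::tibble(x = rnorm(n), z = rnorm(n),
                      y = 0.6 * x + rnorm(n))
  red <- backward_eliminate(fit_lm(d, "y", c("x", "z")))
  expect_identical(red$terms, "x")
  trace <- attr(red, "trace")
  expect_identical(trace$dropped[2], "z")
  # strongly predictive model is left untouched
  d2 <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  d2$y <- 0.7 * d2$a - 0.7 * d2$b + rnorm(n, 0, 0.5)
  full <- fit_lm(d2, "y", c("a", "b"))
  expect_identical(backward_eliminate(full)$terms, c("a", "b"))
})

test_that("elimination agrees with exhaustive best-subset AIC search", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 80
    d <- tibble::tibble(p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n))
    betas <- sample(c(0, 0, 0.5, 0.8), 3)
    d$y <- as.matrix(d) %*% betas + rnorm(n)
    red <- backward_eliminate(fit_lm(d, "y", c("p1", "p2", "p3")))
    subsets <- unlist(lapply(1:3, function(k) {
      combn(c("p1", "p2", "p3"), k, simplify = FALSE)
    }), recursive = FALSE)
    aics <- purrr::map_dbl(subsets, ~ glance(fit_lm(d, "y", .x))$aic)
    best <- subsets[[which.min(aics)]]
    expect_setequal(red$terms, best)
  }
})

test_that("elimination never removes a term whose deletion worsens AIC", {
  set.seed(55)
  d <- tibble::tibble(a = rnorm(120), b = rnorm(120), c = rnorm(120))
  d$y <- 0.5 * d$a + 0.2 * d$b + rnorm(120)
  red <- backward_eliminate(fit_lm(d, "y", c("a", "b", "c")))
  trace <- attr(red, "trace")
  expect_true(all(diff(trace$aic) < 0))
  final_aic <- glance(red)$aic
  for (tm in red$terms) {
    smaller <- fit_lm(red$data, "y", setdiff(red$terms, tm))
    expect_gte(glance(smaller)$aic, final_aic)
  }
})

test_that("p-value elimination mode drops non-significant terms", {
  set.seed(77)
  d <- tibble::tibble(x = rnorm(150), z = rnorm(150))
  d$y <- 0.8 * d$x + rnorm(150)
  red <- backward_eliminate(fit_lm(d, "y", c("x", "z")), criterion = "p")
  expect_identical(red$terms, "x")
})

test_that("nested-model comparison matches the extra-sum-of-squares formula", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(33), z = rnorm(33))
  d$y <- 0.5 * d$x + 0.4 * d$z + rnorm(33)
  full <- fit_lm(d, "y", c("x", "z"))
  reduced <- fit_lm(d, "y", "x")
  cmp <- compare_nested(reduced, full)
  rss_r <- sum(resid(reduced$fit_raw)^2)
  rss_f <- sum(resid(full$fit_raw)^2)
  expect_equal(cmp$f_stat, (rss_r - rss_f) / (rss_f / 30), tolerance = 1e-12)
  expect_equal(cmp$df1, 1L)
  expect_equal(cmp$df2, 30L)
  # independent cross-check against anova()
  av <- anova(reduced$fit_raw, full$fit_raw)
  expect_equal(cmp$f_stat, av$F[2], tolerance = 1e-12)
  expect_equal(cmp$p, av$`Pr(>F)`[2], tolerance = 1e-12)
  # identical models compare as F = 0
  self <- compare_nested(full, full)
  expect_equal(self$f_stat, 0)
  expect_error(compare_nested(full, reduced), class = "minimuse_not_nested")
})

test_that("interaction models build centred products", {
  set.seed(14)
  n <- 120
  d <- tibble::tibble(mef = rnorm(n, 20, 5), rhythm = rnorm(n, 8, 2))
  d$phon <- 0.3 * d$rhythm + 0.05 * (d$mef - 20) * (d$rhythm - 8) + rnorm(n)
  expect_warning(interaction_fit(d, "phon", "mef", "rhythm"),
                 class = "minimuse_no_main_effects")
  fit <- suppressWarnings(interaction_fit(d, "phon", "mef", "rhythm"))
  expect_identical(fit$terms, "mef_x_rhythm")
  # the centred product's mean is exactly the (n-1)/n-scaled covariance,
  # hence near zero for near-orthogonal variables
  prod_col <- fit$data$mef_x_rhythm
  expect_equal(mean(prod_col), cov(d$mef, d$rhythm) * (n - 1) / n,
               tolerance = 1e-10)
  expect_lt(abs(mean(prod_col)) / sd(prod_col), 0.2)
  # definitional equivalence: same fit on a precomputed product column
  d2 <- d
  d2$prod <- (d2$mef - mean(d2$mef)) * (d2$rhythm - mean(d2$rhythm))
  ref <- fit_lm(d2, "phon", "prod")
  expect_equal(tidy(fit)$beta_std, tidy(ref)$beta_std, tolerance = 1e-12)
  expect_equal(glance(fit)$r2, glance(ref)$r2, tolerance = 1e-12)
  # conventional specification with main effects
  fit2 <- interaction_fit(d, "phon", "mef", "rhythm", main_effects = TRUE)
  expect_setequal(fit2$terms, c("mef", "rhythm", "mef_x_rhythm"))
})

test_that("null interactions stay near zero across seeds", {
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    n <- 80
    d <- tibble::tibble(m = rnorm(n), s = rnorm(n))
    d$y <- 0.4 * d$s + rnorm(n)
    fit <- suppressWarnings(interaction_fit(d, "y", "m", "s"))
    if (abs(tidy(fit)$t[1]) < 2) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("simple-slopes points follow the prediction formula", {
  # b0 = 1, b_skill = 2, b_interaction = 0.5, unit SDs, zero means
  set.seed(31)
  n <- 400
  d <- tibble::tibble(m = rnorm(n), s = rnorm(n))
  d$y <- 1 + 2 * d$s + 0.5 * d$m * d$s
  fit <- suppressWarnings(
    interaction_fit(d, "y", "m", "s", covariates = character(),
                    main_effects = TRUE))
  pts <- simple_slopes_points(fit)
  co <- coef(fit$fit_raw)
  sdm <- sd(d$m)
  sds <- sd(d$s)
  mm <- mean(d$m)
  ms <- mean(d$s)
  for (i in seq_len(4)) {
    xs <- ms + ifelse(pts$skill_level[i] == "high", 1, -1) * sds
    xm <- mm + ifelse(pts$moderator_level[i] == "high", 1, -1) * sdm
    pred <- co[["(Intercept)"]] + co[["m"]] * xm + co[["s"]] * xs +
      co[["m_x_s"]] * (xm - mm) * (xs - ms)
    expect_equal(pts$predicted[i], unname(pred), tolerance = 1e-8)
  }
  # zero interaction coefficient makes the two lines parallel
  d$y2 <- 1 + 2 * d$s + rnorm(n, 0, 1e-8)
  fit0 <- suppressWarnings(interaction_fit(d, "y2", "m", "s",
                                           main_effects = TRUE))
  p0 <- simple_slopes_points(fit0)
  slope_low <- diff(p0$predicted[p0$moderator_level == "low"])
  slope_high <- diff(p0$predicted[p0$moderator_level == "high"])
  expect_equal(slope_low, slope_high, tolerance = 1e-4)
  expect_s3_class(plot_simple_slopes(fit), "ggplot")
})

test_that("standardized effects are recovered across simulated studies", {
  est <- matrix(NA_real_, 100, 2)
  for (seed in 1:100) {
    set.seed(seed)
    n <- 200
    d <- tibble::tibble(a = rnorm(n), b = rnorm(n))
    d$y <- 0.5 * d$a + 0.3 * d$b + rnorm(n, 0, sqrt(1 - 0.5^2 - 0.3^2))
    td <- tidy(fit_lm(d, "y", c("a", "b")))
    est[seed, ] <- td$beta_std
  }
  expect_lt(abs(mean(est[, 1]) - 0.5), 0.1)
  expect_lt(abs(mean(est[, 2]) - 0.3), 0.1)
})
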