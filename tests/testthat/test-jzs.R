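test_that("R-squared matches a naive normal-equations solution", {
  set.seed(201)
  n <- 50; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(0.5, -0.3, 0.2) + rnorm(n)
  # brute-force normal equations with explicit intercept
  Z <- cbind(1, X)
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  rss <- sum((y - Z %*% beta)^2)
  brute <- 1 - rss / sum((y - mean(y))^2)
  expect_equal(r_squared(y, X), brute, tolerance = 1e-10)

  # perfect fit limit and orthogonal outcome
  expect_gt(r_squared(as.numeric(X %*% c(1, 2, 3)), X), 1 - 1e-10)
  resid_y <- residuals(lm(rnorm(n) ~ X))
  expect_equal(r_squared(as.numeric(resid_y), X), 0, tolerance = 1e-10)
  expect_error(r_squared(y, cbind(X, X[, 1])), "collinear")
})

test_that("the design builder standardizes, encodes factors, and checks rank", {
  set.seed(202)
  df <- data.frame(y = rnorm(40), x = rnorm(40), w = rnorm(40),
                   f = sample(letters[1:4], 40, replace = TRUE))
  d <- design_spec(df, "y", c("x", "f", "x:w"))
  expect_equal(d$p, 5L)                       # 1 + (4-1) + 1
  expect_equal(d$kinds, c("continuous", rep("factor", 3), "interaction"))
  expect_lt(max(abs(colMeans(d$X))), 1e-10)   # all columns centered
  expect_equal(sd(d$X[, "x"]), 1, tolerance = 1e-12)
  # orthonormal sum-to-zero contrasts: L-1 columns, unit norm, zero sum
  C <- dyadisc:::orthonormal_contrasts(4)
  expect_equal(crossprod(C), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(C), rep(0, 3), tolerance = 1e-12)

  df$x2 <- 2 * df$x + 1
  expect_error(design_spec(df, "y", c("x", "x2")), "collinear")
  expect_error(design_spec(df, "y", c("x", "f:x")), "continuous parents")
  small <- data.frame(y = rnorm(6), x = rnorm(6),
                      f = rep(c("a", "b", "c", "d"), length.out = 6))
  expect_error(design_spec(small, "y", c("x", "f")), "exceed p")
  dfna <- df; dfna$x[1] <- NA
  expect_error(design_spec(dfna, "y", "x"), "missing values")
})

test_that("quadrature reproduces independently computed JZS Bayes factors", {
  # frozen oracle values computed with an independent integrator; the
  # r_scale = 1, p = 1 cases equal the published JZS correlation BF
  cases <- list(
    list(n = 60, p = 3, R2 = 0.30, r = sqrt(2) / 4, bf = 175.324248082),
    list(n = 40, p = 1, R2 = 0.20, r = sqrt(2) / 4, bf = 10.5513327641),
    list(n = 58, p = 9, R2 = 0.50, r = sqrt(2) / 4, bf = 488.661812715),
    list(n = 60, p = 1, R2 = 0.00, r = sqrt(2) / 4, bf = 0.262350794941),
    list(n = 30, p = 2, R2 = 0.05, r = sqrt(2) / 4, bf = 0.271423314428),
    list(n = 60, p = 1, R2 = 0.16, r = 1, bf = 14.79152754),
    list(n = 20, p = 1, R2 = 0.09, r = 1, bf = 0.3881096261),
    list(n = 30, p = 1, R2 = 0.25, r = 1, bf = 7.146625895))
  for (cs in cases) {
    d <- design_with_r2(cs$n, cs$p, cs$R2, seed = 203)
    res <- jzs_bf(d, prior = jzs_prior(r_scale = cs$r))
    expect_equal(res$bf10, cs$bf, tolerance = 1e-6)
    expect_equal(res$r_squared, cs$R2, tolerance = 1e-10)
    expect_equal(res$bf10, exp(res$log_bf10))
  }
})

test_that("null data bound: BF is below one whenever R-squared is zero", {
  for (cfg in list(c(20, 1), c(60, 3), c(100, 5))) {
    d <- design_with_r2(cfg[1], cfg[2], 0, seed = 204)
    expect_lt(jzs_bf(d)$bf10, 1)
  }
})

test_that("BF increases strictly with R-squared at fixed n and p", {
  grid <- seq(0, 0.9, by = 0.1)
  bfs <- vapply(grid, function(R2)
    jzs_bf(design_with_r2(60, 2, R2, seed = 205))$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("the intercept-only null has BF exactly one", {
  df <- data.frame(y = rnorm(30))
  res <- jzs_bf(design_spec(df, "y", character(0)))
  expect_identical(res$bf10, 1)
  expect_identical(res$log_bf10, 0)
})

test_that("BF is invariant to affine transforms of predictors and outcome", {
  set.seed(206)
  df <- data.frame(y = rnorm(50), x = rnorm(50), w = rnorm(50),
                   f = sample(c("u", "v"), 50, replace = TRUE))
  bf1 <- jzs_bf(design_spec(df, "y", c("x", "w", "f")))$bf10
  df2 <- df
  df2$y <- 3.2 * df$y - 40
  df2$x <- -0.7 * df$x + 5
  df2$w <- 100 * df$w
  bf2 <- jzs_bf(design_spec(df2, "y", c("x", "w", "f")))$bf10
  expect_equal(bf1, bf2, tolerance = 1e-8)
})

test_that("degenerate perfect fits are refused", {
  set.seed(207)
  df <- data.frame(x = rnorm(30))
  df$y <- 2 * df$x + 1
  expect_error(jzs_bf(design_spec(df, "y", "x")), "degenerate")
})

test_that("Monte Carlo agrees with quadrature and is seed-reproducible", {
  for (s in 1:3) {
    d <- random_instance(60, 3, seed = 300 + s)
    q <- jzs_bf(d, method = "quadrature")
    m <- jzs_bf(d, method = "monte_carlo", mc_iterations = 200000L,
                seed = 400 + s)
    err <- 3 * (m$bf10 * m$numerical_error + q$bf10 * q$numerical_error)
    expect_lt(abs(q$bf10 - m$bf10), err)
    m2 <- jzs_bf(d, method = "monte_carlo", mc_iterations = 200000L,
                 seed = 400 + s)
    expect_identical(m$bf10, m2$bf10)         # bit-reproducible
  }
})

test_that("BF ratios are reciprocal, transitive, and guard their row sets", {
  set.seed(208)
  df <- data.frame(y = rnorm(45), x = rnorm(45), w = rnorm(45),
                   v = rnorm(45))
  a <- jzs_bf(design_spec(df, "y", "x"))
  b <- jzs_bf(design_spec(df, "y", c("x", "w")))
  c3 <- jzs_bf(design_spec(df, "y", c("x", "w", "v")))
  expect_equal(bf_ratio(a, a), 1)
  expect_equal(bf_ratio(a, b) * bf_ratio(b, a), 1, tolerance = 1e-12)
  expect_equal(bf_ratio(a, c3), bf_ratio(a, b) * bf_ratio(b, c3),
               tolerance = 1e-12)
  expect_equal(bf_ratio(a, b), a$bf10 / b$bf10, tolerance = 1e-12)
  other <- jzs_bf(design_spec(df[1:40, ], "y", "x"))
  expect_error(bf_ratio(a, other), "different row sets")
})

test_that("evidence bands follow the conventional cut points", {
  expect_equal(interpret_band(5.30), "moderate")
  expect_equal(interpret_band(257.99), "extreme")
  expect_equal(interpret_band(1.0), "anecdotal")    # left-closed at 1
  expect_equal(interpret_band(0.4), "against")
  expect_equal(interpret_band(3), "moderate")       # left-closed at 3
  expect_equal(interpret_band(10), "strong")        # left-closed at 10
  expect_equal(interpret_band(100), "strong")       # 100 still strong
  expect_equal(interpret_band(100.5), "extreme")
  expect_equal(interpret_band(c(2, 50)), c("anecdotal", "strong"))
  expect_error(interpret_band(0), "positive")
  expect_error(interpret_band(-2), "positive")
})

test_that("prior sensitivity sweeps include the default and obey limits", {
  d <- design_with_r2(60, 2, 0.2, seed = 209)
  tab <- prior_sensitivity(d, scales = c(0.1, 0.5, 1))
  expect_true(any(abs(tab$scale - sqrt(2) / 4) < 1e-12))
  default_row <- tab[abs(tab$scale - sqrt(2) / 4) < 1e-12, ]
  expect_equal(default_row$bf10, jzs_bf(d)$bf10, tolerance = 1e-8)

  # prior collapse: BF -> 1 as the scale shrinks to zero (the deviation
  # decays linearly in the scale)
  shrink <- prior_sensitivity(d, scales = 10^-(1:6))
  small <- shrink[shrink$scale < 0.2, ]
  dev <- abs(small$bf10 - 1)[order(small$scale, decreasing = TRUE)]
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[length(dev)], 0.01)

  # on null data, wider priors only hurt: BF decreasing in scale
  d0 <- design_with_r2(60, 2, 0, seed = 210)
  null_tab <- prior_sensitivity(d0, scales = c(0.1, 0.25, 0.5, 1, 2))
  expect_true(all(diff(null_tab$bf10[order(null_tab$scale)]) < 0))

  expect_error(prior_sensitivity(d, numeric(0)), "nonempty")
  expect_error(prior_sensitivity(d, c(0.5, -1)), "positive")

  # named model sets get per-scale rankings
  d2 <- design_with_r2(60, 2, 0.4, seed = 211)
  ranks <- prior_sensitivity(list(weak = d, strong = d2),
                             scales = c(0.2, 0.8))
  expect_true(all(ranks$rank[ranks$model == "strong"] == 1))
})
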