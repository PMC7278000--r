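losses <- c("linear", "square", "exponential")

test_that("loss shapes match their closed forms and stay in [0,1]", {
  expect_equal(pgms:::boost_loss(3, 3, "linear"), 1)
  expect_equal(pgms:::boost_loss(3, 3, "square"), 1)
  expect_equal(pgms:::boost_loss(3, 3, "exponential"), 1 - exp(-1))
  for (k in losses) expect_equal(pgms:::boost_loss(0, 3, k), 0)
  set.seed(40)
  l <- runif(50, 0, 7)
  den <- 7
  expect_equal(pgms:::boost_loss(l, den, "linear"), l / den)
  expect_equal(pgms:::boost_loss(l, den, "square"), (l / den)^2)
  expect_equal(pgms:::boost_loss(l, den, "exponential"), 1 - exp(-l / den))
  for (k in losses) {
    v <- pgms:::boost_loss(l, den, k)
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("average loss and confidence follow their formulas", {
  expect_equal(pgms:::boost_average_loss(c(0, 0), c(0.5, 0.5)), 0)
  expect_equal(pgms:::boost_average_loss(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(41)
  L <- runif(30)
  D <- runif(30); D <- D / sum(D)
  expect_equal(pgms:::boost_average_loss(L, D), sum(L * D), tolerance = 1e-12)
  expect_equal(pgms:::boost_beta(0.25), 1 / 3)
  expect_equal(pgms:::boost_beta(0), 1e-10)  # clamp for perfect rounds
  av <- runif(20, 0.01, 0.49)
  expect_equal(vapply(av, pgms:::boost_beta, numeric(1)), av / (1 - av))
})

test_that("weight update multiplies by beta^(alpha(1-L)) then renormalizes", {
  D <- rep(0.25, 4)
  # hardest example (L = 1) keeps its weight factor beta^0 = 1
  up <- pgms:::boost_update_weights(D, 0.5, c(1, 0, 0, 0), 1)
  raw <- c(0.25 * 1, rep(0.25 * 0.5, 3))
  expect_equal(up, raw / sum(raw), tolerance = 1e-12)
  set.seed(42)
  for (rep in 1:5) {
    D <- runif(20); D <- D / sum(D)
    L <- runif(20)
    beta <- runif(1, 0.05, 0.95)
    alpha <- runif(1, 0.01, 1)
    up <- pgms:::boost_update_weights(D, beta, L, alpha)
    expect_equal(sum(up), 1, tolerance = 1e-12)
    raw <- D * beta^(alpha * (1 - L))
    expect_equal(up, raw / sum(raw), tolerance = 1e-12)
  }
  # alpha = 1 reduces to the original update
  D <- runif(10); D <- D / sum(D)
  L <- runif(10)
  expect_equal(pgms:::boost_update_weights(D, 0.3, L, 1),
               {r <- D * 0.3^(1 - L); r / sum(r)}, tolerance = 1e-14)
})

test_that("weighted median equals the brute-force infimum rule", {
  expect_equal(weighted_median(5, 2), 5)
  expect_equal(weighted_median(rep(3.3, 7), runif(7, 0.1, 1)), 3.3)
  set.seed(43)
  for (rep in 1:20) {
    t_ <- sample(1:9, 1)
    preds <- rnorm(t_, 0, 20)
    betas <- runif(t_, 1e-6, 1 - 1e-6)
    w <- log(1 / betas)
    expect_equal(weighted_median(preds, w),
                 oracle_weighted_median(preds, betas), tolerance = 1e-12)
  }
  # permutation invariance and boundedness
  preds <- rnorm(7); w <- runif(7)
  p <- sample(7)
  expect_equal(weighted_median(preds, w), weighted_median(preds[p], w[p]))
  expect_true(weighted_median(preds, w) >= min(preds))
  expect_true(weighted_median(preds, w) <= max(preds))
})

test_that("fits are deterministic and weight bookkeeping stays valid", {
  toy <- make_toy_pairs(80, seed = 44)
  x <- toy$noninvasive_mgdl
  d <- toy$invasive_mgdl - x
  a <- adaboost_r2(x, d, n_estimators = 30, max_depth = 4, seed = 5)
  b <- adaboost_r2(x, d, n_estimators = 30, max_depth = 4, seed = 5)
  expect_identical(predict(a, x), predict(b, x))
  expect_true(all(a$betas > 0 & a$betas < 1))
  expect_true(length(a$trees) >= 1)
})

test_that("constant differences are learned exactly", {
  x <- seq(80, 300, length.out = 40)
  fit <- adaboost_r2(x, rep(12, 40), n_estimators = 10, max_depth = 3,
                     seed = 1)
  expect_equal(predict(fit, c(50, 150, 400)), rep(12, 3))
  expect_equal(predict_glucose(fit, c(100, 200)), c(112, 212))
  # d == 0 gives z == x
  fit0 <- adaboost_r2(x, rep(0, 40), n_estimators = 5, seed = 1)
  expect_equal(predict_glucose(fit0, x), x)
})

test_that("alpha = 1 agrees with an independent AdaBoost.R2 transcription", {
  toy <- make_toy_pairs(100, seed = 45, sigma = 0.04)
  x <- toy$noninvasive_mgdl
  d <- toy$invasive_mgdl - x
  for (loss in losses) {
    mine <- adaboost_r2(x, d, n_estimators = 25, max_depth = 4, alpha = 1,
                        loss = loss, seed = 7)
    ref <- oracle_adaboost_fit(x, d, n_estimators = 25, max_depth = 4,
                               loss = loss, seed = 7)
    expect_equal(length(mine$trees), length(ref$trees))
    grid <- seq(min(x), max(x), length.out = 60)
    agree <- abs(predict(mine, grid) - oracle_adaboost_predict(ref, grid))
    expect_gte(mean(agree < 1e-6), 0.95)
  }
})

test_that("weighted-median ensemble predictions match brute force", {
  toy <- make_toy_pairs(60, seed = 46)
  x <- toy$noninvasive_mgdl
  d <- toy$invasive_mgdl - x
  fit <- adaboost_r2(x, d, n_estimators = 15, max_depth = 3, alpha = 0.5,
                     loss = "square", seed = 3)
  grid <- seq(min(x), max(x), length.out = 25)
  for (x0 in grid) {
    preds <- vapply(fit$trees, tree_predict, numeric(1), newx = x0)
    expect_equal(predict(fit, x0),
                 oracle_weighted_median(preds, fit$betas, fit$alpha))
  }
})

test_that("noise-free systematic error is driven below 1% training MARD", {
  set.seed(47)
  y <- runif(250, 70, 450)
  bias <- -0.35 + 0.6 * (y - 70) / 380          # smooth, monotone in y
  x <- y * (1 - bias)
  d <- y - x
  fit <- adaboost_r2(x, d, n_estimators = 200, max_depth = 10, seed = 2)
  z <- predict_glucose(fit, x)
  expect_lt(mard(y, z), 1)
})

test_that("degenerate first round is kept with a warning flag", {
  # targets depend on an unobservable coin flip: no weak model beats 0.5
  set.seed(48)
  x <- rep(c(1, 2), each = 4)
  d <- c(-100, 100, -100, 100, -100, 100, -100, 100) + rnorm(8, 0, 1e-6)
  fit <- adaboost_r2(x, d, n_estimators = 10, max_depth = 1, seed = 1)
  expect_true(fit$n_rounds >= 1)
  expect_true(is.finite(predict(fit, 1.5)))
})

test_that("models serialize to JSON and reload with identical predictions", {
  toy <- make_toy_pairs(50, seed = 49)
  x <- toy$noninvasive_mgdl
  d <- toy$invasive_mgdl - x
  fit <- adaboost_r2(x, d, n_estimators = 12, max_depth = 4,
                     loss = "exponential", alpha = 0.7, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_adaboost_json(fit, path)
  back <- read_adaboost_json(path)
  grid <- seq(min(x), max(x), length.out = 40)
  expect_equal(predict(back, grid), predict(fit, grid), tolerance = 1e-12)
  expect_equal(back$betas, fit$betas, tolerance = 1e-12)
})
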