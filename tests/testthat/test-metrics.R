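test_that("signed error follows the (ref - v)/ref convention", {
  expect_equal(signed_error(100, 100), 0)
  expect_equal(signed_error(100, 321), -221)
  expect_equal(signed_error(100, 80), 20)
  set.seed(1)
  ref <- runif(200, 40, 500)
  v <- ref * runif(200, 0.3, 3)
  expect_equal(signed_error(ref, v), oracle_signed_error(ref, v),
               tolerance = 1e-12)
  expect_error(signed_error(0, 100), "positive")
  expect_error(signed_error(-5, 100), "positive")
})

test_that("MARD matches its definition on trivial and random inputs", {
  expect_equal(mard(c(100, 200), c(100, 200)), 0)
  expect_equal(mard(c(100, 200), c(80, 240)), 20)
  set.seed(2)
  ref <- runif(1000, 40, 500)
  vals <- ref * runif(1000, 0.5, 2)
  expect_equal(mard(ref, vals), oracle_mard(ref, vals), tolerance = 1e-9)
  expect_error(mard(numeric(0), numeric(0)), "empty")
  expect_error(mard(1:3, 1:2), "length")
})

test_that("MARD is invariant under common rescaling", {
  set.seed(3)
  ref <- runif(50, 50, 400)
  vals <- ref * runif(50, 0.5, 1.5)
  expect_equal(mard(ref, vals), mard(2.37 * ref, 2.37 * vals),
               tolerance = 1e-12)
})

test_that("RMSE of differences matches a direct computation", {
  expect_equal(rmse_diff(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse_diff(5, 2), 3)
  set.seed(4)
  d <- rnorm(300, 0, 30)
  dp <- d + rnorm(300, 0, 5)
  expect_equal(rmse_diff(d, dp), oracle_rmse(d, dp), tolerance = 1e-9)
  expect_error(rmse_diff(numeric(0), numeric(0)), "empty")
})

test_that("weighted aggregation reproduces pooled statistics on partitions", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 200
    ref <- runif(n, 50, 400)
    vals <- ref * runif(n, 0.6, 1.6)
    g <- sample(1:4, n, replace = TRUE)
    m_j <- tabulate(g, 4)
    mard_j <- vapply(1:4, function(j) mard(ref[g == j], vals[g == j]),
                     numeric(1))
    expect_equal(overall_mard(m_j, mard_j), mard(ref, vals),
                 tolerance = 1e-12)
    d <- ref - vals
    rmse_j <- vapply(1:4, function(j) rmse_diff(d[g == j], rep(0, m_j[j])),
                     numeric(1))
    expect_equal(overall_rmse(m_j, rmse_j), rmse_diff(d, rep(0, n)),
                 tolerance = 1e-12)
  }
  expect_equal(overall_mard(7, 12.5), 12.5)
  expect_equal(overall_rmse(c(3, 3), c(3, 4)), sqrt(12.5))
  expect_error(overall_mard(c(0, 0), c(1, 2)), "zero")
})

test_that("error summary panels agree with their independent formulas", {
  y <- c(100, 200)
  v <- c(110, 190)  # signed errors -10 and +5
  s <- error_summary(y, v)
  expect_equal(s$min_error, -10)
  expect_equal(s$max_error, 5)
  expect_equal(s$mard, 7.5)
  expect_equal(s$n, 2L)

  set.seed(6)
  ref <- runif(150, 50, 450)
  vals <- ref * runif(150, 0.5, 1.8)
  s <- error_summary(ref, vals)
  e <- oracle_signed_error(ref, vals)
  expect_equal(s$mard, mean(abs(e)), tolerance = 1e-12)
  expect_equal(s$min_error, min(e), tolerance = 1e-12)
  expect_equal(s$max_error, max(e), tolerance = 1e-12)
  expect_equal(s$rmse, oracle_rmse(ref, vals), tolerance = 1e-9)
  expect_true(s$mard <= max(abs(s$min_error), abs(s$max_error)))

  z <- error_summary(ref, ref)
  expect_equal(c(z$mard, z$min_error, z$max_error, z$rmse), rep(0, 4))
})
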