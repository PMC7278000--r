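test_that("constant targets give a single-leaf tree", {
  tr <- tree_fit(c(1, 2, 3, 4), rep(7, 4), max_depth = 5)
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(tree_predict(tr, c(-10, 2.5, 100)), rep(7, 3))
})

test_that("degenerate features return the weighted mean, not an error", {
  tr <- tree_fit(rep(5, 4), c(1, 2, 3, 10), w = c(1, 1, 1, 1))
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(tree_predict(tr, 5), 4)
  trw <- tree_fit(rep(5, 2), c(0, 10), w = c(3, 1))
  expect_equal(tree_predict(trw, 5), 2.5)
})

test_that("depth-1 splits match the exhaustive midpoint search", {
  set.seed(30)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    x <- round(runif(n, 0, 10), 2)
    y <- rnorm(n)
    w <- runif(n, 0.2, 2)
    if (length(unique(x)) < 2) next
    tr <- tree_fit(x, y, w, max_depth = 1)
    best <- oracle_best_split(x, y, w)
    expect_equal(unname(tr$nodes[1, "threshold"]), best$threshold)
    lo <- min(x) - 1; hi <- max(x) + 1
    expect_equal(tree_predict(tr, lo), best$left, tolerance = 1e-12)
    expect_equal(tree_predict(tr, hi), best$right, tolerance = 1e-12)
  }
})

test_that("a deep tree interpolates distinct points exactly", {
  set.seed(31)
  x <- sample(seq(1, 300, by = 3))
  y <- sin(x / 20) * 50
  tr <- tree_fit(x, y, max_depth = 25)
  expect_equal(tree_predict(tr, x), y, tolerance = 1e-10)
})

test_that("weighted splits agree with rpart on shared settings", {
  skip_if_not_installed("rpart")
  set.seed(32)
  x <- runif(80, 0, 100)
  y <- 0.5 * x + rnorm(80, 0, 5)
  w <- runif(80, 0.5, 2)
  tr <- tree_fit(x, y, w, max_depth = 1)
  rp <- rpart::rpart(y ~ x, weights = w, method = "anova",
                     control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                    minsplit = 2,
                                                    minbucket = 1,
                                                    xval = 0))
  expect_equal(unname(tr$nodes[1, "threshold"]), rp$splits[1, "index"],
               tolerance = 1e-8)
})
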