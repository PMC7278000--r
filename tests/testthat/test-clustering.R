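test_that("domain clusters partition the positive axis", {
  sch <- domain_scheme()
  expect_equal(nrow(sch), 6L)
  expect_equal(sch$lower[-1], sch$upper[-6])  # contiguous
  set.seed(20)
  g <- runif(500, 1, 600)
  idx <- assign_cluster(g)
  expect_false(anyNA(idx))
  expect_true(all(g > sch$lower[idx] & g <= sch$upper[idx]))
})

test_that("named range examples and boundary conventions hold", {
  sch <- domain_scheme()
  expect_equal(sch$cluster[assign_cluster(95)], "No diabetic")
  expect_equal(sch$cluster[assign_cluster(162)], "Diabetic")
  expect_equal(sch$cluster[assign_cluster(80)], "Hypoglycemia")
  expect_equal(sch$cluster[assign_cluster(80.5)], "No diabetic")
  expect_equal(sch$cluster[assign_cluster(37)], "Hypoglycemia")
  expect_equal(sch$cluster[assign_cluster(490)], "Critically diabetic")
  expect_error(assign_cluster(0), "positive")
})

test_that("k-means k=1 collapses to the mean", {
  v <- c(60, 100, 150, 300)
  km <- kmeans_1d(v, 1)
  expect_equal(km$centers, mean(v))
  expect_equal(km$inertia, sum((v - mean(v))^2))
  expect_equal(km$labels, rep(1L, 4))
})

test_that("well-separated point masses separate perfectly", {
  v <- c(rep(70, 10), rep(300, 10))
  km <- kmeans_1d(v, 2, seed = 3)
  expect_equal(km$inertia, 0)
  expect_equal(sort(km$centers), c(70, 300))
  expect_equal(length(unique(km$labels[v == 70])), 1L)
})

test_that("small-n solutions are bounded below by the exhaustive optimum", {
  set.seed(21)
  for (rep in 1:5) {
    v <- runif(8, 40, 400)
    km <- kmeans_1d(v, 2, seed = rep)
    opt <- oracle_kmeans2_optimum(v)
    expect_gte(km$inertia, opt - 1e-8)
    expect_lte(km$inertia, opt * 3 + 1e-8)  # sane, near-optimal clustering
  }
})

test_that("k-means is deterministic under a fixed seed and inertia is monotone", {
  set.seed(22)
  v <- runif(60, 40, 400)
  a <- kmeans_1d(v, 4, seed = 9)
  b <- kmeans_1d(v, 4, seed = 9)
  expect_identical(a$centers, b$centers)
  expect_identical(a$labels, b$labels)

  # Lloyd from a fixed initialization: within-cluster SS after i iterations
  # is non-increasing in i
  init <- matrix(sort(v)[c(5, 20, 40, 55)], ncol = 1)
  inertia <- vapply(1:8, function(i) {
    suppressWarnings(stats::kmeans(v, centers = init, iter.max = i,
                                   algorithm = "Lloyd"))$tot.withinss
  }, numeric(1))
  expect_true(all(diff(inertia) <= 1e-8))

  expect_error(kmeans_1d(c(1, 1, 1), 2), "distinct")
})
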