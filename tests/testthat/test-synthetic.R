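test_that("spec constructors validate their invariants", {
  expect_error(dataset_spec(5, c(60, 400), c(60, 400), 20, c(-100, 50)),
               "n_pairs")
  expect_error(dataset_spec(100, c(400, 60), c(60, 400), 20, c(-100, 50)),
               "min < max")
  expect_error(dataset_spec(100, c(60, 400), c(60, 400), 20, c(100, 150)),
               "bracket zero")
  expect_error(dataset_spec(100, c(60, 400), c(60, 400), 120, c(-100, 50)),
               "MARD")
  s <- dataset1_spec()
  expect_equal(s$n_pairs, 918L)
  expect_equal(s$error_range, c(-221, 61))
})

test_that("anchor pairs are feasible and hit the extremes exactly", {
  for (spec in list(dataset1_spec(), dataset2_spec())) {
    a <- default_anchor_pairs(spec)
    expect_equal(nrow(a), 6L)
    expect_true(all(a$invasive_mgdl >= spec$invasive_range[1] &
                    a$invasive_mgdl <= spec$invasive_range[2]))
    expect_true(all(a$noninvasive_mgdl >= spec$noninvasive_range[1] &
                    a$noninvasive_mgdl <= spec$noninvasive_range[2]))
    e <- oracle_signed_error(a$invasive_mgdl, a$noninvasive_mgdl)
    expect_equal(min(e), spec$error_range[1])
    expect_equal(max(e), spec$error_range[2])
  }
  # an impossible extreme errors out naming the constraint
  bad <- dataset_spec(100, c(60, 70), c(300, 400), 30, c(-50, 40))
  expect_error(default_anchor_pairs(bad), "not realizable")
})

test_that("generated datasets reproduce their spec marginals", {
  for (spec in list(dataset1_spec(), dataset2_spec())) {
    d <- generate_dataset(spec, seed = 1)
    expect_equal(nrow(d), spec$n_pairs)
    v <- validate_against_spec(d, spec)
    expect_true(attr(v, "pass"))
    e <- oracle_signed_error(d$invasive_mgdl, d$noninvasive_mgdl)
    expect_equal(min(e), spec$error_range[1])
    expect_equal(max(e), spec$error_range[2])
  }
})

test_that("zero noise and zero bias give an identity error model", {
  spec <- dataset_spec(50, c(60, 400), c(20, 500), 10, c(-50, 30),
                       name = "identity")
  cfg <- generator_config(spec,
                          bias_knots = cbind(c(60, 400), c(0, 0)),
                          noise_sigma = 0,
                          anchor_pairs = NULL)
  d <- generate_dataset(spec, cfg, seed = 3)
  expect_equal(d$noninvasive_mgdl, d$invasive_mgdl, tolerance = 1e-12)
  expect_equal(mard(d$invasive_mgdl, d$noninvasive_mgdl), 0)
})

test_that("the generator's reported MARD equals a brute-force recount", {
  spec <- dataset1_spec()
  for (s in 1:5) {
    d <- generate_dataset(spec, seed = s)
    expect_equal(attr(d, "realized_mard"),
                 oracle_mard(d$invasive_mgdl, d$noninvasive_mgdl),
                 tolerance = 1e-9)
  }
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- dataset2_spec()
  set.seed(99)
  before <- .Random.seed
  a <- generate_dataset(spec, seed = 7)
  expect_identical(.Random.seed, before)
  b <- generate_dataset(spec, seed = 7)
  expect_identical(a$invasive_mgdl, b$invasive_mgdl)
  expect_identical(a$noninvasive_mgdl, b$noninvasive_mgdl)
  c_ <- generate_dataset(spec, seed = 8)
  expect_false(identical(a$noninvasive_mgdl, c_$noninvasive_mgdl))
})

test_that("marginal fidelity holds across seeds within the 1% band", {
  for (spec in list(dataset1_spec(), dataset2_spec())) {
    hits <- vapply(1:5, function(s) {
      d <- generate_dataset(spec, seed = s)
      abs(mard(d$invasive_mgdl, d$noninvasive_mgdl) - spec$target_mard) <= 1
    }, logical(1))
    expect_gte(sum(hits), 4)
  }
})

test_that("a perfect systematic correction leaves only the noise floor", {
  # with sigma = 0.09, E|N(0, sigma)| ~ 7.2%: correcting by the true bias
  # curve must land the residual MARD in the learnable band [5, 10]%
  for (spec in list(dataset1_spec(), dataset2_spec())) {
    d <- generate_dataset(spec, seed = 2)
    b <- attr(d, "bias_fun")
    y <- d$invasive_mgdl
    corrected <- d$noninvasive_mgdl + y * b(y)
    resid <- mard(y, corrected)
    expect_gte(resid, 5)
    expect_lte(resid, 10)
  }
})

test_that("validation reports failures with realized values", {
  spec <- dataset1_spec()
  tiny <- data.frame(invasive_mgdl = 100, noninvasive_mgdl = 100)
  v <- validate_against_spec(tiny, spec)
  expect_false(attr(v, "pass"))
  expect_equal(v$realized[v$check == "mard"], 0)
  expect_false(v$pass[v$check == "n_pairs"])
})
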