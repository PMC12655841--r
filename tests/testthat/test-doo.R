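test_that("train/test split has the documented proportions and is seeded", {
  s <- makeSplit(10, seed = 3)
  expect_length(s$train, 8L)
  expect_length(s$test, 2L)
  expect_identical(makeSplit(10, seed = 3)$train, s$train)
  s2 <- makeSplit(1020, seed = 99)
  expect_length(s2$train, 816L)
  expect_length(s2$test, 204L)
  expect_identical(sort(c(s2$train, s2$test)), 1:1020)
  expect_length(intersect(s2$train, s2$test), 0L)
  expect_false(identical(makeSplit(1020, 1)$train, makeSplit(1020, 2)$train))
  expect_error(makeSplit(9, 1), "at least 10")
})

test_that("standardization maps train columns to mean 0 / sd 1 and reuses the map", {
  tr <- matrix(c(2, 4, 6), ncol = 1, dimnames = list(NULL, "a"))
  std <- standardizeFeatures(tr)
  expect_equal(as.numeric(std$train), c(-1, 0, 1) * 2 / 2, tolerance = 1e-4)
  expect_equal(as.numeric(std$train), (c(2, 4, 6) - 4) / 2)

  set.seed(11)
  x <- matrix(stats::rnorm(60, mean = 5, sd = 3), 20, 3)
  other <- matrix(stats::rnorm(15, mean = 5, sd = 3), 5, 3)
  std <- standardizeFeatures(x, other)
  expect_true(all(abs(colMeans(std$train)) < 1e-9))
  expect_true(all(abs(apply(std$train, 2, stats::sd) - 1) < 1e-9))
  ## the test block uses TRAIN means/sds, not its own
  expect_equal(
    std$other,
    sweep(sweep(other, 2, colMeans(x), "-"), 2, apply(x, 2, stats::sd), "/")
  )
  ## applying the stored map to the train set reproduces it
  expect_equal(
    sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/"),
    std$train
  )
  xc <- cbind(x, const = 7)
  expect_warning(std2 <- standardizeFeatures(xc), "constant")
  expect_identical(ncol(std2$train), 3L)
  expect_error(
    suppressWarnings(standardizeFeatures(matrix(1, 5, 2))),
    "constant"
  )
})

test_that("gamma anchor is the reciprocal median pairwise squared distance", {
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE) # distance 5
  expect_equal(gammaBase(two), 1 / 25)
  ## three collinear points with pairwise squared distances {1, 9, 4}
  three <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(gammaBase(three), 1 / 4)
  ## exhaustive pair-enumeration oracle on a random matrix
  set.seed(2)
  x <- matrix(stats::rnorm(40), 10, 4)
  d2 <- as.numeric(stats::dist(x))^2
  expect_equal(gammaBase(x), 1 / stats::median(d2), tolerance = 1e-12)
  ## translation invariance and c^-2 scale covariance
  expect_equal(gammaBase(x + 100), gammaBase(x), tolerance = 1e-9)
  expect_equal(gammaBase(3 * x), gammaBase(x) / 9, tolerance = 1e-12)
  expect_error(gammaBase(matrix(1, 4, 2)), "duplicate")
})

test_that("trial evaluation honours the nu-SVR contract", {
  syn <- generateSynthetic(syntheticSpec(n_records = 120, seed = 5))
  x <- featureMatrix(syn$table)
  y <- targetValues(syn$table)
  tr <- evaluateTrial(x, y, hyperParams(0.4, 10, 0), folds = 5, seed = 1)
  expect_identical(tr$status, "ok")
  expect_length(tr$fold_maes, 5L)
  expect_true(all(tr$fold_sv_ratios > 0 & tr$fold_sv_ratios <= 1))
  expect_true(tr$sv_ratio >= 0.4 - 0.02)
  expect_gte(tr$cv_mae, 0)
  ## deterministic under a fixed seed
  tr2 <- evaluateTrial(x, y, hyperParams(0.4, 10, 0), folds = 5, seed = 1)
  expect_identical(tr$fold_maes, tr2$fold_maes)
})

test_that("a constant response is fit to near-zero CV error", {
  set.seed(9)
  x <- matrix(stats::rnorm(200), 50, 4)
  y <- rep(2.5, 50)
  tr <- evaluateTrial(x, y, hyperParams(0.1, 1, 0), folds = 5, seed = 2)
  expect_lt(tr$cv_mae, 1e-6)
})

test_that("the dual-objective search is seeded, bounded, and complete", {
  syn <- generateSynthetic(syntheticSpec(n_records = 100, seed = 8))
  x <- featureMatrix(syn$table)[, 1:6]
  y <- targetValues(syn$table)
  one <- runDoo(x, y, n_trials = 1, seed = 4)
  expect_identical(nrow(one$table), 1L)
  expect_identical(formals(runDoo)$n_trials, 2000L) # protocol default
  d1 <- runDoo(x, y, n_trials = 25, seed = 4)
  d2 <- runDoo(x, y, n_trials = 25, seed = 4)
  expect_identical(d1$table, d2$table)
  expect_false(identical(d1$table$nu, runDoo(x, y, 25, seed = 5)$table$nu))
  ok <- d1$table$status == "ok"
  expect_true(all(d1$table$nu >= 0.05 & d1$table$nu <= 0.95))
  expect_true(all(d1$table$C >= 1e-2 & d1$table$C <= 1e3))
  expect_true(all(d1$table$sv_ratio[ok] > 0 & d1$table$sv_ratio[ok] <= 1))
  expect_identical(ncol(d1$fold_maes), 5L)
})

test_that("the Pareto front keeps exactly the non-dominated trials", {
  single <- makeTrials(0.5, 0.5)
  expect_identical(paretoFront(single)$table$trial_id, 1L)
  ## worked example: {(1,.5),(2,.4),(3,.3),(2,.6)} -> first three
  tr <- makeTrials(c(1, 2, 3, 2), c(0.5, 0.4, 0.3, 0.6))
  expect_identical(sort(paretoFront(tr)$table$trial_id), 1:3)
  ## duplicates on both objectives are all retained
  dup <- makeTrials(c(1, 1, 2), c(0.5, 0.5, 0.2))
  expect_identical(sort(paretoFront(dup)$table$trial_id), 1:3)
  ## a strictly dominated solution never appears
  dom <- makeTrials(c(1, 2), c(0.3, 0.5))
  expect_identical(paretoFront(dom)$table$trial_id, 1L)
  expect_error(paretoFront(makeTrials(1, 0.5, status = "failed")), "no successful")
})

test_that("the front matches the brute-force domination oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    mae <- round(stats::runif(n, 0, 1), sample(c(1, 3), 1)) # ties likely
    svr <- round(stats::runif(n, 0.01, 1), sample(c(1, 3), 1))
    got <- sort(paretoFront(makeTrials(mae, svr))$table$trial_id)
    expect_identical(got, sort(bruteForceFront(mae, svr)))
  }
})
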