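test_that("aggregation computes per-count frequencies and moments", {
  traces <- lapply(1:10, function(r) {
    makeFakeTrace(r, counts = 8:6, test_maes = c(0.10, 0.09, 0.11) + r / 100)
  })
  rep_ <- aggregateRuns(traces)
  expect_s3_class(rep_, "stabilityReport")
  expect_identical(rep_$n_runs, 10L)
  expect_equal(rep_$counts$frequency[rep_$counts$count == 8], 1.0)
  ## mean/sd at each count match a direct recomputation
  maes7 <- vapply(traces, function(tr) {
    tr$candidates[[2L]]$test_mae
  }, numeric(1L))
  expect_equal(rep_$counts$mean_test_mae[rep_$counts$count == 7], mean(maes7))
  expect_equal(rep_$counts$sd_test_mae[rep_$counts$count == 7], stats::sd(maes7))
  expect_error(aggregateRuns(traces[1L]), ">= 2")
})

test_that("counts missing from some traces dilute the frequency", {
  ## 3 of 10 runs reach count 12, the rest stop at 8
  traces <- c(
    lapply(1:3, function(r) makeFakeTrace(r, c(12L, 8L), c(0.10, 0.11))),
    lapply(4:10, function(r) makeFakeTrace(r, 8L, 0.11))
  )
  rep_ <- aggregateRuns(traces)
  expect_equal(rep_$counts$frequency[rep_$counts$count == 12], 0.3)
  expect_equal(rep_$counts$n_runs_at[rep_$counts$count == 12], 3L)
  expect_equal(rep_$counts$frequency[rep_$counts$count == 8], 1.0)
})

test_that("aggregation is invariant to run order and degenerate under copies", {
  traces <- lapply(1:6, function(r) {
    makeFakeTrace(r, counts = 9:7, test_maes = c(0.12, 0.1, 0.14) + r / 50)
  })
  a <- aggregateRuns(traces)
  b <- aggregateRuns(rev(traces))
  expect_equal(a$counts, b$counts)
  copies <- lapply(1:5, function(r) makeFakeTrace(r, 9:7, c(0.12, 0.1, 0.14)))
  cc <- aggregateRuns(copies)
  expect_true(all(cc$counts$sd_test_mae == 0))
  expect_true(all(cc$counts$frequency == 1))
  expect_true(all(unlist(cc$descriptor_freq) == 1))
})

test_that("architectural selection enforces frequency then the 1-SE band", {
  ## hand-walked: over 25 runs, count 8 (freq .6, MAE .090, sd .010),
  ## count 9 (freq .5, MAE .092), count 14 (freq .2, MAE .089):
  ## SE = .010/sqrt(15) = .00258 -> threshold .09258 -> {8, 9}; 14 fails
  ## the frequency bar despite the lowest MAE.
  report <- structure(
    list(
      n_runs = 25L,
      counts = data.frame(
        count = c(8L, 9L, 14L),
        frequency = c(0.6, 0.5, 0.2),
        n_runs_at = c(15L, 13L, 5L),
        mean_test_mae = c(0.090, 0.092, 0.089),
        sd_test_mae = c(0.010, 0.012, 0.008),
        mean_train_mae = c(0.08, 0.08, 0.08),
        mean_test_r2 = c(0.95, 0.94, 0.95)
      ),
      descriptor_freq = list()
    ),
    class = "stabilityReport"
  )
  sel <- architecturalSelection(report)
  expect_identical(sel, c(8L, 9L))
  expect_true(all(
    report$counts$frequency[report$counts$count %in% sel] >= 0.30
  ))
  ## a single dominating count is returned alone
  report$counts$mean_test_mae <- c(0.090, 0.2, 0.3)
  report$counts$frequency <- c(1, 0.4, 0.2)
  expect_identical(architecturalSelection(report), 8L)
  ## nothing clears the bar -> warning + global-minimum fallback
  report$counts$frequency <- c(0.1, 0.1, 0.1)
  expect_warning(fb <- architecturalSelection(report), "frequency threshold")
  expect_identical(fb, 8L)
})

test_that("composite scores min-max normalize the three criteria at 50/30/20", {
  A <- makeFakeCandidate(8, test_mae = 0.08, train_mae = 0.07, test_r2 = 0.97)
  B <- makeFakeCandidate(8, test_mae = 0.10, train_mae = 0.07, test_r2 = 0.94)
  sA <- compositeScore(A, list(A, B))
  sB <- compositeScore(B, list(A, B))
  expect_equal(sA$total, 1.0) # best on all three raw metrics
  expect_equal(sB$total, 0.0)
  expect_equal(sA$accuracy_component, 1)
  expect_equal(sA$r2_component, 1)
  expect_equal(sA$generalization_component, 1)
  ## weights are exactly 0.5 / 0.3 / 0.2
  C <- makeFakeCandidate(8, test_mae = 0.08, train_mae = 0.07, test_r2 = 0.94)
  sC <- compositeScore(C, list(A, B, C))
  expect_equal(sC$total, 0.5 * 1 + 0.3 * 0 + 0.2 * 1)
  ## single-member cohort scores 1 everywhere
  s1 <- compositeScore(A, list(A))
  expect_equal(s1$total, 1.0)
})

test_that("improving one raw metric never lowers the composite total", {
  base <- makeFakeCandidate(8, test_mae = 0.10, train_mae = 0.08, test_r2 = 0.90)
  other <- makeFakeCandidate(8, test_mae = 0.12, train_mae = 0.09, test_r2 = 0.85)
  better_r2 <- base
  better_r2$test_r2 <- 0.95
  t0 <- compositeScore(base, list(base, other))$total
  t1 <- compositeScore(better_r2, list(better_r2, other))$total
  expect_gte(t1, t0)
})

test_that("final selection prefers composite score, then descriptor stability", {
  feats_common <- sprintf("D%02d", 1:8)
  feats_rare <- c(sprintf("D%02d", 1:7), "D99")
  ## run 1 (common descriptors) and run 5 (one rare descriptor) tie exactly
  ## on every raw metric; runs 2-4 are clearly worse. The near-tie must be
  ## broken by descriptor stability: D01..D08 occur in 4-5 of 5 runs, D99
  ## in only one.
  traces <- c(
    lapply(1:4, function(r) {
      makeFakeTrace(r, 8L, if (r == 1L) 0.1000 else 0.1000 + r / 1000,
                    features_by_count = list(feats_common))
    }),
    list(makeFakeTrace(5L, 8L, 0.1000, features_by_count = list(feats_rare)))
  )
  rep_ <- aggregateRuns(traces)
  fin <- finalSelection(rep_, traces)
  expect_s3_class(fin, "finalModel")
  expect_identical(fin$candidate$n_features, 8L)
  expect_identical(fin$provenance$run_id, 1L)
  expect_identical(fin$candidate$feature_names, feats_common)
  expect_gt(fin$stability, max(
    fin$cohort$descriptor_stability[fin$cohort$run_id == 5L]
  ))
  ## single-candidate cohort returns that candidate
  solo <- list(
    makeFakeTrace(1L, 8L, 0.1), makeFakeTrace(2L, 8L, 0.1)
  )
  fs <- finalSelection(aggregateRuns(solo), solo)
  expect_identical(fs$candidate$n_features, 8L)
})
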