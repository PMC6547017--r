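test_that("the default correlation matrix matches the data model", {
  spec <- correlation_spec()
  R <- build_correlation_matrix(spec)

  expect_identical(dim(R), c(13L, 13L))
  expect_identical(colnames(R), c("Y", "X", paste0("Z", 1:11)))
  expect_equal(unname(diag(R)), rep(1, 13))
  expect_identical(R, t(R))
  expect_identical(R["Y", "X"], 0.6)
  expect_equal(unname(R["Y", c("Z1", "Z2")]), c(0.4, 0.4))
  expect_equal(unname(R["Y", paste0("Z", 3:7)]), rep(0.2, 5))
  expect_equal(unname(R["Y", paste0("Z", 8:11)]), rep(0.1, 4))
  # all non-outcome pairs uncorrelated
  expect_equal(unname(R[-1, -1] - diag(12)), matrix(0, 12, 12))
  # positive definite (eigendecomposition oracle)
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("invalid correlation structures are rejected", {
  expect_error(correlation_spec(c(X = 1.0)), "inside")
  # sum of squared correlations >= 1 breaks positive definiteness
  expect_error(
    correlation_spec(c(X = 0.8, Z1 = 0.7)),
    "positive definite"
  )
  expect_error(correlation_spec(c(Y = 0.5)), "unique names")
})

test_that("cohort simulation is seed-deterministic and leaves the RNG alone", {
  spec <- correlation_spec(n = 50)
  set.seed(42)
  before <- .Random.seed
  a <- simulate_cohort(spec, seed = 7)
  expect_identical(.Random.seed, before)
  b <- simulate_cohort(spec, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, simulate_cohort(spec, seed = 8)$values))
  expect_identical(colnames(a$values), c("Y", "X", paste0("Z", 1:11)))
  expect_false(anyNA(a$values))
})

test_that("sample correlations of a cohort match their targets within MC tolerance", {
  ch <- simulate_cohort(correlation_spec(n = 1000), seed = 314)
  v <- ch$values
  # SE of a sample correlation is about (1 - rho^2) / sqrt(n)
  expect_lt(abs(cor(v[, "Y"], v[, "X"]) - 0.6), 0.08)
  expect_lt(abs(cor(v[, "Z1"], v[, "Z2"])), 0.10)
})

test_that("a large cohort reproduces the full target correlation matrix", {
  spec <- correlation_spec(n = 1e5)
  R <- build_correlation_matrix(spec)
  v <- simulate_cohort(spec, seed = 2718)$values
  Rhat <- cor(v)
  # 4 SEs per entry: 156 off-diagonal comparisons, so 3 SEs would give a
  # ~1/3 family-wise false-alarm rate; 4 SEs keeps it around 1%
  tol <- 4 * (1 - R^2) / sqrt(1e5)
  expect_true(all(abs(Rhat - R) <= tol + diag(13)))
  # means 0, SDs 1 within 3 / sqrt(n) and 3 / sqrt(2n)
  expect_true(all(abs(colMeans(v)) < 3 / sqrt(1e5)))
  expect_true(all(abs(apply(v, 2, sd) - 1) < 3 / sqrt(2 * 1e5)))
})

test_that("multiple_r2 is the closed-form sum of squared outcome correlations", {
  spec <- correlation_spec()
  expect_identical(multiple_r2(spec, "X"), 0.36)
  expect_equal(multiple_r2(spec, c("X", "Z3")), 0.40)
  expect_equal(multiple_r2(spec, c("X", "Z1")), 0.52)
  expect_equal(multiple_r2(spec, c("X", "Z1", "Z2", "Z3", "Z4")), 0.76)
  expect_equal(multiple_r2(spec, c("X", paste0("Z", 1:11))), 0.92)
  expect_warning(r0 <- multiple_r2(spec, character(0)), "no information")
  expect_identical(r0, 0)
  expect_error(multiple_r2(spec, c("X", "W9")), "unknown")
})

test_that("multiple_r2 is additive over disjoint predictor sets", {
  spec <- correlation_spec()
  vars <- names(spec$outcome_correlations)
  set.seed(11)
  for (i in 1:20) {
    a <- sample(vars, sample(1:6, 1))
    b <- sample(setdiff(vars, a), sample(1:4, 1))
    expect_equal(
      multiple_r2(spec, c(a, b)),
      multiple_r2(spec, a) + multiple_r2(spec, b)
    )
  }
})

test_that("cohorts round-trip through CSV", {
  spec <- correlation_spec(n = 25)
  ch <- simulate_cohort(spec, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ch, path)
  back <- read_cohort_csv(path)
  expect_s3_class(back, "cohort")
  expect_equal(back$values, ch$values, tolerance = 1e-12)

  masked <- apply_mcar(ch, 0.2)
  write_cohort_csv(masked, path)
  back <- read_cohort_csv(path)
  expect_s3_class(back, "masked_cohort")
  expect_identical(back$missing_mask, masked$missing_mask)
  expect_equal(back$values, masked$values, tolerance = 1e-12)
})
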