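make_masked <- function(n = 200, p = 0.2, seed = 1, spec = correlation_spec(n = n)) {
  apply_mcar(simulate_cohort(spec, seed), p)
}

test_that("imputation model specs enforce the analysis-model nesting rule", {
  expect_error(imputation_model("bad", c("Z1", "Z2")), "add 'X'")
  expect_error(imputation_model("bad", "X", m = 1), "m must be")

  mods <- default_imputation_models(m = 5)
  expect_named(mods, paste("model", 1:5))
  expect_identical(mods[["model 1"]]$predictors, "X")
  expect_identical(mods[["model 2"]]$predictors, c("X", "Z3"))
  expect_identical(mods[["model 3"]]$predictors, c("X", "Z1"))
  expect_identical(mods[["model 4"]]$predictors, c("X", paste0("Z", 1:4)))
  expect_identical(mods[["model 5"]]$predictors, c("X", paste0("Z", 1:11)))
  # auxiliary information ladder is strictly increasing
  spec <- correlation_spec()
  r2 <- vapply(mods, function(mo) multiple_r2(spec, mo$predictors), numeric(1))
  expect_equal(unname(r2), c(0.36, 0.40, 0.52, 0.76, 0.92))
})

test_that("the observed-data regression recovers exact and population slopes", {
  # noiseless: Y is an exact linear function of X
  vals <- cbind(Y = 3 + 2 * (1:20), X = 1:20, Z1 = rnorm(20))
  masked <- structure(
    list(values = vals, missing_mask = rep(FALSE, 20)),
    class = "masked_cohort"
  )
  fit <- fit_observed_regression(masked, imputation_model("lin", "X", m = 2))
  expect_equal(unname(fit$beta_hat), c(3, 2), tolerance = 1e-10)
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-18)

  # population slope of Y on X alone is Cov(Y, X) / Var(X) = 0.6
  masked <- make_masked(n = 20000, p = 0.1, seed = 42)
  fit <- fit_observed_regression(masked, imputation_model("m1", "X", m = 2))
  expect_equal(unname(fit$beta_hat["X"]), 0.6, tolerance = 0.02)
  expect_equal(fit$sigma2_hat, 0.64, tolerance = 0.02)
  expect_identical(fit$n_complete, 18000L)
  expect_identical(fit$residual_df, 18000L - 2L)

  # too few complete rows for the parameter count
  tiny <- apply_mcar(simulate_cohort(correlation_spec(n = 14), seed = 2), 0.2)
  expect_error(
    fit_observed_regression(tiny, imputation_model("m5", c("X", paste0("Z", 1:11)), m = 2)),
    "complete rows"
  )
})

test_that("posterior draws follow the noninformative-prior posterior", {
  masked <- make_masked(n = 52, p = 1 / 52, seed = 9)
  fit <- fit_observed_regression(masked, imputation_model("m3", c("X", "Z1"), m = 2))
  nd <- 1e5
  d <- withr::with_seed(123, fmisim:::draw_posterior_matrix(fit, nd))

  # E[beta*] = beta_hat, checked coordinatewise at 3 empirical SEs
  for (j in seq_along(fit$beta_hat)) {
    expect_lt(
      abs(mean(d$beta_star[j, ]) - fit$beta_hat[j]),
      3 * sd(d$beta_star[j, ]) / sqrt(nd)
    )
  }
  # E[sigma*^2] = sigma2_hat * nu / (nu - 2) (inverse-chi-squared mean)
  nu <- fit$residual_df
  s2 <- d$sigma_star^2
  expect_lt(
    abs(mean(s2) - fit$sigma2_hat * nu / (nu - 2)),
    3 * sd(s2) / sqrt(nd)
  )
  expect_true(all(d$sigma_star > 0))

  # degenerate fit: zero residual variance collapses to the point estimate
  vals <- cbind(Y = 2 * (1:30), X = 1:30)
  exact <- structure(
    list(values = vals, missing_mask = rep(FALSE, 30)),
    class = "masked_cohort"
  )
  dfit <- fit_observed_regression(exact, imputation_model("m1", "X", m = 2))
  one <- draw_posterior(dfit)
  expect_identical(one$sigma_star, 0)
  expect_equal(one$beta_star, dfit$beta_hat)
})

test_that("imputed stacks fill only masked cells, reproducibly", {
  masked <- make_masked(n = 100, p = 0.3, seed = 4)
  mod <- imputation_model("m3", c("X", "Z1"), m = 10)
  st <- impute_stack(masked, mod, seed = 77)
  st2 <- impute_stack(masked, mod, seed = 77)
  expect_identical(st$imputed_y, st2$imputed_y)

  mis <- masked$missing_mask
  for (j in c(1, 5, 10)) {
    comp <- complete_data(st, j)
    expect_false(anyNA(comp))
    expect_identical(comp[!mis, ], masked$values[!mis, ])
    expect_identical(comp[, -1], masked$values[, -1])
  }
  # filled values for a masked row differ across imputations
  expect_true(all(apply(st$imputed_y, 1, function(r) length(unique(r)) > 1)))

  # nothing to impute: all copies identical to the source
  none <- apply_mcar(simulate_cohort(correlation_spec(n = 50), seed = 1), 0)
  st0 <- impute_stack(none, imputation_model("m1", "X", m = 3), seed = 1)
  expect_identical(complete_data(st0, 2), none$values)

  # long-format audit export
  lg <- stack_long(st)
  expect_identical(nrow(lg), 10L * sum(mis))
  expect_identical(lg$Y[lg$imputation == 3], unname(st$imputed_y[, 3]))
})

test_that("imputed values are centred on the conditional mean with inflated spread", {
  # one masked row, many imputations
  spec <- correlation_spec(n = 200)
  masked <- apply_mcar(simulate_cohort(spec, seed = 31), 1 / 200)
  mod <- imputation_model("m3", c("X", "Z1"), m = 1000)
  st <- impute_stack(masked, mod, seed = 8)
  fit <- st$fit
  cond_mean <- drop(c(1, masked$values[1, c("X", "Z1")]) %*% fit$beta_hat)
  filled <- st$imputed_y[1, ]
  # law of total expectation: mean filled value ~= beta_hat . covariates
  expect_lt(abs(mean(filled) - cond_mean), 3 * sd(filled) / sqrt(1000))

  # proper imputation inflates the spread beyond the residual variance:
  # parameter uncertainty adds to residual noise (checked on 1e4 draws
  # from a small fit where the inflation is well above MC noise)
  masked30 <- apply_mcar(simulate_cohort(correlation_spec(n = 30), seed = 6), 1 / 30)
  mod30 <- imputation_model("m1", "X", m = 1e4)
  st30 <- impute_stack(masked30, mod30, seed = 13)
  expect_gte(var(st30$imputed_y[1, ]), st30$fit$sigma2_hat)
})
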