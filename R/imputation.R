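#' Specify a linear-regression imputation model
#'
#' The imputation model regresses the (partially observed) outcome on an
#' intercept plus the listed predictors. The predictor set must contain the
#' exposure `X` so that the imputation model nests the analysis model; any
#' further variables are auxiliaries included to recover information about
#' the missing outcomes.
#'
#' @param label Short label used in result tables (e.g. `"model 3"`).
#' @param predictors Character vector of predictor labels; must include
#'   `"X"`.
#' @param m Number of imputations (at least 2).
#' @return An object of class `imputation_model_spec`.
#' @seealso [default_imputation_models()] for the standard five-model
#'   ladder of increasing auxiliary information.
#' @export
imputation_model <- function(label, predictors, m = 1000L) {
  predictors <- as.character(predictors)
  if (!"X" %in% predictors) {
    stop("the imputation model must contain every analysis-model variable; add 'X'")
  }
  if (anyDuplicated(predictors)) stop("duplicated predictors")
  m <- as.integer(m)
  if (is.na(m) || m < 2L) stop("m must be an integer >= 2")
  structure(
    list(label = as.character(label), predictors = predictors, m = m),
    class = "imputation_model_spec"
  )
}

#' The standard five-model auxiliary-information ladder
#'
#' Five nested-information imputation models for the default data model,
#' ordered by the outcome variance their predictors explain:
#' model 1 `{X}` (R^2 = 0.36, no auxiliary information), model 2 `{X, Z3}`
#' (0.40), model 3 `{X, Z1}` (0.52), model 4 `{X, Z1..Z4}` (0.76) and
#' model 5 `{X, Z1..Z11}` (0.92). Models 3--5 contain `Z1` and therefore
#' every variable in the MAR selection mechanism; models 1--2 do not.
#'
#' @param m Number of imputations for every model.
#' @param labels Optional subset of labels to return.
#' @return A named list of [imputation_model()] specs.
#' @export
default_imputation_models <- function(m = 1000L, labels = NULL) {
  sets <- list(
    "model 1" = "X",
    "model 2" = c("X", "Z3"),
    "model 3" = c("X", "Z1"),
    "model 4" = c("X", paste0("Z", 1:4)),
    "model 5" = c("X", paste0("Z", 1:11))
  )
  if (!is.null(labels)) {
    unknown <- setdiff(labels, names(sets))
    if (length(unknown)) stop("unknown model labels: ", paste(unknown, collapse = ", "))
    sets <- sets[labels]
  }
  lapply(names(sets), function(lbl) imputation_model(lbl, sets[[lbl]], m = m)) |>
    stats::setNames(names(sets))
}

#' Fit the imputation regression on the complete rows
#'
#' Ordinary least squares of the observed outcome on an intercept plus the
#' model's predictors, over the rows with observed `Y`. Returns everything
#' the posterior sampler needs: the coefficient estimates, the residual
#' variance (residual-df corrected), the inverse cross-product matrix and
#' the residual degrees of freedom.
#'
#' @param masked A `masked_cohort`.
#' @param spec An [imputation_model()].
#' @return An object of class `imputation_fit` with elements `beta_hat`,
#'   `sigma2_hat`, `xtx_inverse`, `residual_df`, `n_complete`, `spec`.
#' @export
fit_observed_regression <- function(masked, spec) {
  stopifnot(inherits(masked, "masked_cohort"), inherits(spec, "imputation_model_spec"))
  obs <- !masked$missing_mask
  k <- length(spec$predictors) + 1L
  if (sum(obs) <= k) {
    stop(sprintf(
      "need more than %d complete rows to fit %d coefficients; have %d",
      k, k, sum(obs)
    ))
  }
  X <- cbind(`(Intercept)` = 1, masked$values[obs, spec$predictors, drop = FALSE])
  y <- masked$values[obs, "Y"]
  qrX <- qr(X)
  if (qrX$rank < k) stop("singular imputation design matrix")
  beta_hat <- qr.coef(qrX, y)
  resid <- y - drop(X %*% beta_hat)
  df <- sum(obs) - k
  sigma2_hat <- sum(resid^2) / df
  Rmat <- qr.R(qrX)
  xtx_inverse <- chol2inv(Rmat)
  dimnames(xtx_inverse) <- list(colnames(X), colnames(X))
  structure(
    list(
      beta_hat = beta_hat, sigma2_hat = sigma2_hat,
      xtx_inverse = xtx_inverse, residual_df = df,
      n_complete = sum(obs), spec = spec
    ),
    class = "imputation_fit"
  )
}

#' Draw imputation-model parameters from their posterior
#'
#' Proper imputation requires the filled values to reflect parameter
#' uncertainty. Under the standard noninformative prior for the normal
#' linear model, the residual variance posterior is scaled inverse
#' chi-squared, `sigma*^2 = sigma2_hat * df / chi2(df)`, and the
#' coefficients are `beta* ~ N(beta_hat, sigma*^2 * (X'X)^-1)`.
#'
#' @param fit An [fit_observed_regression()] result.
#' @return A `posterior_draw`: list with `beta_star` and `sigma_star`.
#' @export
draw_posterior <- function(fit) {
  d <- draw_posterior_matrix(fit, 1L)
  structure(
    list(beta_star = drop(d$beta_star), sigma_star = d$sigma_star),
    class = "posterior_draw"
  )
}

# Vectorised sampler: m joint draws of (beta*, sigma*). Columns of
# beta_star index draws. Degenerate fits (sigma2_hat = 0) collapse to the
# point estimate.
draw_posterior_matrix <- function(fit, m) {
  k <- length(fit$beta_hat)
  if (fit$sigma2_hat <= 0) {
    return(list(
      beta_star = matrix(fit$beta_hat, k, m, dimnames = list(names(fit$beta_hat), NULL)),
      sigma_star = numeric(m)
    ))
  }
  sigma_star <- sqrt(fit$sigma2_hat * fit$residual_df / stats::rchisq(m, fit$residual_df))
  U <- chol(fit$xtx_inverse)
  z <- matrix(stats::rnorm(k * m), k, m)
  beta_star <- fit$beta_hat + t(U) %*% z * rep(sigma_star, each = k)
  rownames(beta_star) <- names(fit$beta_hat)
  list(beta_star = beta_star, sigma_star = sigma_star)
}

#' Multiply impute the missing outcome values
#'
#' For each of `m` imputations an independent posterior draw of the
#' imputation-model parameters fills every missing outcome with
#' `beta* . covariates + N(0, sigma*^2)` noise. Observed values are never
#' touched, so the `m` completed datasets agree on every observed entry and
#' differ only in the filled cells.
#'
#' @param masked A `masked_cohort`.
#' @param spec An [imputation_model()].
#' @param seed Integer RNG seed.
#' @return An `imputed_stack`: the source data, the missingness mask, and an
#'   `n_missing x m` matrix of imputed outcome values. Use
#'   [complete_data()] to materialise any single completed dataset.
#' @export
impute_stack <- function(masked, spec, seed) {
  fit <- fit_observed_regression(masked, spec)
  mis <- masked$missing_mask
  n_mis <- sum(mis)
  m <- spec$m
  imputed_y <- with_seed(seed, {
    if (n_mis == 0L) {
      matrix(numeric(0), 0L, m)
    } else {
      draws <- draw_posterior_matrix(fit, m)
      Xmis <- cbind(1, masked$values[mis, spec$predictors, drop = FALSE])
      eps <- matrix(stats::rnorm(n_mis * m), n_mis, m) * rep(draws$sigma_star, each = n_mis)
      Xmis %*% draws$beta_star + eps
    }
  })
  structure(
    list(
      source = masked, imputed_y = imputed_y,
      fit = fit, spec = spec, seed = as.integer(seed)
    ),
    class = "imputed_stack"
  )
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf(
    "<imputed_stack> m = %d imputations of %d missing outcomes (%s: %s)\n",
    x$spec$m, nrow(x$imputed_y), x$spec$label,
    paste(x$spec$predictors, collapse = ", ")
  ))
  invisible(x)
}

#' Materialise one completed dataset from an imputed stack
#'
#' @param stack An [impute_stack()] result.
#' @param j Imputation index in `1..m`.
#' @return The completed `n x (k+1)` data matrix.
#' @export
complete_data <- function(stack, j) {
  stopifnot(inherits(stack, "imputed_stack"))
  j <- as.integer(j)
  if (j < 1L || j > stack$spec$m) stop("imputation index out of range")
  vals <- stack$source$values
  if (nrow(stack$imputed_y) > 0L) {
    vals[stack$source$missing_mask, "Y"] <- stack$imputed_y[, j]
  }
  vals
}

#' Export an imputed stack in long format
#'
#' One row per (imputation, masked row): columns `imputation`, `row`, `Y`.
#' Intended for audit trails, not the hot path.
#'
#' @param stack An [impute_stack()] result.
#' @return A tibble.
#' @export
stack_long <- function(stack) {
  stopifnot(inherits(stack, "imputed_stack"))
  rows <- which(stack$source$missing_mask)
  tibble::tibble(
    imputation = rep(seq_len(stack$spec$m), each = length(rows)),
    row = rep(rows, times = stack$spec$m),
    Y = as.vector(stack$imputed_y)
  )
}
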