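#' Fit the analysis model Y ~ X by ordinary least squares
#'
#' The analysis model is the simple linear regression of the outcome on the
#' exposure, `y = b0 + b1 x + e`. The fit is closed form; sampling
#' variances come from the standard OLS variance estimator. With
#' `complete_rows_only = TRUE` (or when `data` is a `masked_cohort`) rows
#' with missing outcome are dropped, giving the complete case analysis.
#'
#' @param data An `n x k` matrix with columns `Y` and `X` (a `cohort`,
#'   `masked_cohort` or bare matrix).
#' @param complete_rows_only Drop rows with missing `Y` before fitting.
#' @return A `fit_result`: list with `coefficients` (`b0`, `b1`),
#'   `variances`, `sigma2`, `n_used`.
#' @export
fit_analysis_model <- function(data, complete_rows_only = inherits(data, "masked_cohort")) {
  vals <- if (is.matrix(data)) data else data$values
  y <- vals[, "Y"]
  x <- vals[, "X"]
  if (complete_rows_only) {
    keep <- !is.na(y)
    y <- y[keep]
    x <- x[keep]
  } else if (anyNA(y)) {
    stop("data contain missing outcomes; impute them or set complete_rows_only = TRUE")
  }
  n <- length(y)
  if (n < 3L) stop("need at least 3 usable rows to fit the analysis model")
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  if (sxx <= 0) stop("exposure has zero variance in the usable rows")
  ybar <- mean(y)
  b1 <- sum((x - xbar) * (y - ybar)) / sxx
  b0 <- ybar - b1 * xbar
  rss <- sum((y - b0 - b1 * x)^2)
  sigma2 <- rss / (n - 2L)
  structure(
    list(
      coefficients = c(b0 = b0, b1 = b1),
      variances = c(
        b0 = sigma2 * (1 / n + xbar^2 / sxx),
        b1 = sigma2 / sxx
      ),
      sigma2 = sigma2,
      n_used = n
    ),
    class = "fit_result"
  )
}

#' Fit the analysis model to every completed dataset of a stack
#'
#' Vectorised equivalent of calling [fit_analysis_model()] on each of the
#' `m` completed datasets: the exposure column is shared, so the slope,
#' intercept and their OLS variances for all imputations are computed with
#' a handful of matrix operations.
#'
#' @param stack An [impute_stack()] result.
#' @return An `mi_fits` object: `estimates` and `variances` are `2 x m`
#'   matrices with rows `b0`, `b1`.
#' @export
analyse_stack <- function(stack) {
  stopifnot(inherits(stack, "imputed_stack"))
  vals <- stack$source$values
  mis <- stack$source$missing_mask
  m <- stack$spec$m
  n <- nrow(vals)
  x <- vals[, "X"]
  Y <- matrix(vals[, "Y"], n, m)
  if (any(mis)) Y[mis, ] <- stack$imputed_y
  xbar <- mean(x)
  xc <- x - xbar
  sxx <- sum(xc^2)
  ybar <- colMeans(Y)
  b1 <- drop(crossprod(xc, Y)) / sxx # crossprod with centred x drops ybar term
  b0 <- ybar - b1 * xbar
  rss <- colSums(Y^2) - n * ybar^2 - b1^2 * sxx
  sigma2 <- rss / (n - 2L)
  estimates <- rbind(b0 = b0, b1 = b1)
  variances <- rbind(
    b0 = sigma2 * (1 / n + xbar^2 / sxx),
    b1 = sigma2 / sxx
  )
  structure(list(estimates = estimates, variances = variances, m = m), class = "mi_fits")
}

#' Pool per-imputation fits by Rubin's rules
#'
#' For each coefficient: the pooled estimate is the mean of the
#' per-imputation estimates; the within-imputation variance `W` is the mean
#' of the sampling variances; the between-imputation variance `B` is the
#' sample variance of the estimates; and the total variance is
#' `T = W + (1 + 1/m) B`. With `r = (1 + 1/m) B / W`, the classic fraction
#' of missing information is `(1 + 1/m) B / T = r / (1 + r)`, the reference
#' degrees of freedom are `df = (m - 1)(1 + 1/r)^2`, and the df-adjusted
#' FMI -- the form large-sample MI software reports -- is
#' `(r + 2 / (df + 3)) / (r + 1)`. Confidence limits use the t reference
#' distribution on `df`.
#'
#' @param fits A list of [fit_analysis_model()] results (one per
#'   imputation), or an `mi_fits` object from [analyse_stack()].
#' @param conf_level Confidence level for the pooled interval.
#' @return A `pooled_estimate`: a tibble with one row per coefficient and
#'   columns `term`, `estimate`, `W`, `B`, `T`, `se`, `df`, `fmi_classic`,
#'   `fmi_adjusted`, `conf_low`, `conf_high`, `m`.
#' @examples
#' fits <- lapply(1:3, function(i) {
#'   structure(list(coefficients = c(b1 = i), variances = c(b1 = 1)),
#'             class = "fit_result")
#' })
#' pool_rubin(fits)
#' @export
pool_rubin <- function(fits, conf_level = 0.95) {
  if (inherits(fits, "mi_fits")) {
    est <- fits$estimates
    v <- fits$variances
  } else {
    if (!is.list(fits) || length(fits) < 2L) stop("need at least m = 2 fits to pool")
    terms <- names(fits[[1L]]$coefficients)
    if (!all(vapply(fits, function(f) identical(names(f$coefficients), terms), logical(1L)))) {
      stop("all fits must estimate the same coefficients")
    }
    est <- vapply(fits, function(f) f$coefficients, numeric(length(terms)))
    v <- vapply(fits, function(f) f$variances, numeric(length(terms)))
    if (length(terms) == 1L) {
      est <- matrix(est, 1L, dimnames = list(terms))
      v <- matrix(v, 1L, dimnames = list(terms))
    }
  }
  m <- ncol(est)
  if (m < 2L) stop("need at least m = 2 fits to pool")
  q_bar <- rowMeans(est)
  W <- rowMeans(v)
  B <- apply(est, 1L, stats::var)
  Tvar <- W + (1 + 1 / m) * B
  r <- ifelse(W > 0, (1 + 1 / m) * B / W, ifelse(B > 0, Inf, 0))
  fmi_classic <- ifelse(is.infinite(r), 1, ifelse(r == 0, 0, r / (1 + r)))
  df <- ifelse(r > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  fmi_adjusted <- ifelse(
    is.infinite(r), 1,
    (r + 2 / (df + 3)) / (r + 1)
  )
  alpha <- 1 - conf_level
  tq <- ifelse(is.finite(df), stats::qt(1 - alpha / 2, df), stats::qnorm(1 - alpha / 2))
  se <- sqrt(Tvar)
  out <- tibble::tibble(
    term = rownames(est),
    estimate = unname(q_bar),
    W = unname(W), B = unname(B), T = unname(Tvar),
    se = unname(se), df = unname(df),
    fmi_classic = unname(fmi_classic),
    fmi_adjusted = unname(fmi_adjusted),
    conf_low = unname(q_bar - tq * se),
    conf_high = unname(q_bar + tq * se),
    m = m
  )
  class(out) <- c("pooled_estimate", class(out))
  out
}

#' Impute, analyse and pool in one step
#'
#' Convenience wrapper: multiply impute a masked cohort under one
#' imputation model, fit the analysis model to every completed dataset, and
#' pool by Rubin's rules.
#'
#' @inheritParams impute_stack
#' @param conf_level Confidence level passed to [pool_rubin()].
#' @return A `pooled_estimate` tibble.
#' @export
mi_analysis <- function(masked, spec, seed, conf_level = 0.95) {
  pool_rubin(analyse_stack(impute_stack(masked, spec, seed)), conf_level = conf_level)
}
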