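#' Missingness scenario on the outcome
#'
#' Describes how outcome values go missing. Under MCAR the first
#' `round(p * n)` rows are deleted (rows are iid, so this equals random
#' deletion in distribution). Under MAR each row is deleted independently
#' with probability `plogis(alpha + coef_z1 * Z1 + coef_x * X)`: missingness
#' depends on the exposure and the strongest auxiliary, so complete case
#' analysis of `Y ~ X` is biased unless the imputation model recovers `Z1`.
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param p Target proportion of missing outcome data, in `[0, 1)`. Under
#'   MAR this is the proportion achieved on average across datasets.
#' @param alpha Intercept of the MAR selection model. If `NULL` (default) it
#'   is calibrated numerically with [calibrate_alpha()]. Ignored under MCAR.
#' @param coef_z1,coef_x Selection-model coefficients on `Z1` and `X`
#'   (defaults 1, 1).
#' @return An object of class `missingness_scenario`.
#' @export
missingness_scenario <- function(mechanism = c("MCAR", "MAR"), p,
                                 alpha = NULL, coef_z1 = 1, coef_x = 1) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.numeric(p), length(p) == 1L)
  if (p < 0 || p >= 1) stop("target proportion p must lie in [0, 1)")
  if (mechanism == "MCAR") {
    alpha <- NULL
  } else if (is.null(alpha) && p > 0) {
    alpha <- calibrate_alpha(p, coef_z1, coef_x)
  }
  structure(
    list(
      mechanism = mechanism, p = p, alpha = alpha,
      coef_z1 = coef_z1, coef_x = coef_x
    ),
    class = "missingness_scenario"
  )
}

#' @export
print.missingness_scenario <- function(x, ...) {
  if (x$mechanism == "MCAR") {
    cat(sprintf("<missingness_scenario> MCAR, p = %g\n", x$p))
  } else {
    cat(sprintf(
      "<missingness_scenario> MAR, p = %g, logit = %.4f + %g*Z1 + %g*X\n",
      x$p, x$alpha, x$coef_z1, x$coef_x
    ))
  }
  invisible(x)
}

#' Delete the first p*n outcome values (MCAR)
#'
#' @param cohort A [simulate_cohort()] result.
#' @param p Proportion to delete, in `[0, 1)`. The count is `round(p * n)`
#'   with halves rounded away from zero.
#' @return A `masked_cohort`: the cohort's `values` with masked `Y` entries
#'   set to `NA`, plus a logical `missing_mask` of length `n`.
#' @export
apply_mcar <- function(cohort, p) {
  stopifnot(inherits(cohort, "cohort"))
  if (p < 0 || p >= 1) stop("p must lie in [0, 1): p = 1 leaves no complete cases")
  n <- nrow(cohort$values)
  n_miss <- floor(p * n + 0.5) # half-away-from-zero for non-negative p*n
  mask <- rep(FALSE, n)
  if (n_miss > 0L) mask[seq_len(n_miss)] <- TRUE
  new_masked_cohort(cohort, mask)
}

#' Calibrate the MAR selection-model intercept to a target proportion
#'
#' Solves `E[plogis(alpha + coef_z1*Z1 + coef_x*X)] = p_target`, where the
#' linear predictor minus `alpha` is normal with mean 0 and variance
#' `coef_z1^2 + coef_x^2` (the two covariates are independent standard
#' normals under the data model). The expectation is evaluated by adaptive
#' quadrature over the normal density and the root found by
#' [stats::uniroot()]; the achieved proportion matches the target to within
#' `1e-6`.
#'
#' @param p_target Target average missingness proportion, in `(0, 1)`.
#' @param coef_z1,coef_x Selection-model coefficients.
#' @return The calibrated intercept `alpha`.
#' @examples
#' calibrate_alpha(0.5) # exactly 0 by symmetry
#' @export
calibrate_alpha <- function(p_target, coef_z1 = 1, coef_x = 1) {
  stopifnot(is.numeric(p_target), length(p_target) == 1L)
  if (p_target <= 0 || p_target >= 1) stop("p_target must lie strictly in (0, 1)")
  s <- sqrt(coef_z1^2 + coef_x^2)
  expected_prop <- function(a) {
    if (s == 0) return(stats::plogis(a))
    stats::integrate(
      function(z) stats::plogis(a + s * z) * stats::dnorm(z),
      -Inf, Inf, rel.tol = 1e-10
    )$value
  }
  root <- tryCatch(
    stats::uniroot(
      function(a) expected_prop(a) - p_target,
      interval = c(-40, 40), extendInt = "upX", tol = 1e-10
    ),
    error = function(e) {
      stop(sprintf(
        "calibration failed for p_target = %g (coefs %g, %g): %s",
        p_target, coef_z1, coef_x, conditionMessage(e)
      ))
    }
  )
  achieved <- expected_prop(root$root)
  if (abs(achieved - p_target) >= 1e-6) {
    stop(sprintf(
      "calibration did not converge: target %g, achieved %g", p_target, achieved
    ))
  }
  root$root
}

#' Impose MAR missingness on the outcome
#'
#' Each row `i` is masked independently with probability
#' `plogis(alpha + coef_z1 * Z1_i + coef_x * X_i)`. The achieved proportion
#' is random per dataset; no per-dataset renormalisation is applied, so the
#' target is met on average across datasets, which is what a logistic
#' selection mechanism implies.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param scenario A MAR [missingness_scenario()] with calibrated `alpha`.
#' @param seed Integer RNG seed for the Bernoulli draws.
#' @return A `masked_cohort`.
#' @export
apply_mar <- function(cohort, scenario, seed) {
  stopifnot(inherits(cohort, "cohort"), inherits(scenario, "missingness_scenario"))
  if (scenario$mechanism != "MAR") stop("scenario mechanism must be MAR")
  if (scenario$p > 0 && is.null(scenario$alpha)) stop("scenario has no calibrated alpha")
  n <- nrow(cohort$values)
  if (scenario$p == 0) return(new_masked_cohort(cohort, rep(FALSE, n)))
  eta <- scenario$alpha +
    scenario$coef_z1 * cohort$values[, "Z1"] +
    scenario$coef_x * cohort$values[, "X"]
  mask <- with_seed(seed, stats::runif(n) < stats::plogis(eta))
  new_masked_cohort(cohort, mask)
}

new_masked_cohort <- function(cohort, mask) {
  vals <- cohort$values
  vals[mask, "Y"] <- NA_real_
  structure(
    list(values = vals, missing_mask = mask),
    class = "masked_cohort"
  )
}

#' @export
print.masked_cohort <- function(x, ...) {
  cat(sprintf(
    "<masked_cohort> %d x %d, %d/%d outcome values missing\n",
    nrow(x$values), ncol(x$values), sum(x$missing_mask), nrow(x$values)
  ))
  invisible(x)
}
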