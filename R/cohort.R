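#' Population correlation structure for a simulated cohort
#'
#' Defines the joint distribution of a continuous outcome `Y`, an exposure
#' `X`, and auxiliary variables `Z1`--`Z11` (or however many auxiliaries are
#' supplied). All variables are standard normal; only the outcome is
#' correlated with the other variables, which are mutually uncorrelated.
#' This mirrors a prospective cohort in which baseline covariates carry
#' independent pieces of information about a follow-up outcome.
#'
#' The default correlations give `Y`--`X` = 0.6, `Y`--`Z1,Z2` = 0.4,
#' `Y`--`Z3..Z7` = 0.2 and `Y`--`Z8..Z11` = 0.1, so the full predictor set
#' explains R^2 = 0.92 of the outcome variance.
#'
#' @param outcome_correlations Named numeric vector of correlations between
#'   the outcome and each other variable, in column order. Names default to
#'   `X`, `Z1`, `Z2`, ... when unnamed.
#' @param n Cohort size (number of individuals).
#'
#' @return An object of class `correlation_spec`.
#' @examples
#' spec <- correlation_spec()
#' multiple_r2(spec, c("X", "Z1"))
#' @export
correlation_spec <- function(outcome_correlations = c(
                               X = 0.6,
                               Z1 = 0.4, Z2 = 0.4,
                               Z3 = 0.2, Z4 = 0.2, Z5 = 0.2, Z6 = 0.2, Z7 = 0.2,
                               Z8 = 0.1, Z9 = 0.1, Z10 = 0.1, Z11 = 0.1
                             ),
                             n = 1000L) {
  stopifnot(is.numeric(outcome_correlations), length(outcome_correlations) >= 1)
  if (is.null(names(outcome_correlations))) {
    k <- length(outcome_correlations)
    names(outcome_correlations) <- c("X", paste0("Z", seq_len(k - 1L)))[seq_len(k)]
  }
  if (anyDuplicated(names(outcome_correlations)) || "Y" %in% names(outcome_correlations)) {
    stop("outcome_correlations must have unique names, none of them 'Y'")
  }
  if (any(abs(outcome_correlations) >= 1)) {
    stop("every outcome correlation must lie strictly inside (-1, 1)")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  spec <- structure(
    list(outcome_correlations = outcome_correlations, n = n),
    class = "correlation_spec"
  )
  # positive definiteness of the implied matrix; with mutually uncorrelated
  # predictors this reduces to sum(rho^2) < 1, but check the matrix itself
  # so the error names the offending configuration
  rho2 <- sum(outcome_correlations^2)
  if (rho2 >= 1) {
    stop(sprintf(
      "implied correlation matrix is not positive definite: sum of squared outcome correlations is %.4f >= 1",
      rho2
    ))
  }
  spec
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat(sprintf(
    "<correlation_spec> %d variables + outcome, n = %d, total R^2 = %.4f\n",
    length(x$outcome_correlations), x$n, sum(x$outcome_correlations^2)
  ))
  invisible(x)
}

#' Build the population correlation matrix implied by a spec
#'
#' The matrix has unit diagonal, the outcome row/column equal to the spec's
#' outcome correlations, and all other off-diagonal entries zero.
#'
#' @param spec A [correlation_spec()].
#' @return A symmetric positive-definite correlation matrix with dimnames
#'   `(Y, X, Z1, ...)`.
#' @export
build_correlation_matrix <- function(spec) {
  stopifnot(inherits(spec, "correlation_spec"))
  rho <- spec$outcome_correlations
  k <- length(rho) + 1L
  R <- diag(k)
  R[1L, -1L] <- rho
  R[-1L, 1L] <- rho
  nms <- c("Y", names(rho))
  dimnames(R) <- list(nms, nms)
  # guard against a spec constructed by hand that bypassed validation
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    stop(sprintf(
      "correlation matrix for spec with correlations (%s) is not positive definite (min eigenvalue %.3g)",
      paste(format(rho), collapse = ", "), ev
    ))
  }
  R
}

#' Simulate a complete cohort from the multivariate-normal data model
#'
#' Draws `spec$n` iid observations from the multivariate normal distribution
#' with mean zero, unit variances, and the correlation matrix implied by the
#' spec. Sampling applies the Cholesky factor of the correlation matrix to
#' iid standard normals, so the target covariance is exact in population and
#' the draw is fully reproducible from the seed.
#'
#' @param spec A [correlation_spec()].
#' @param seed Integer RNG seed; the caller's RNG state is left untouched.
#' @return An object of class `cohort`: a list with `values` (an `n x (k+1)`
#'   numeric matrix with columns `Y, X, Z1, ...`) and `seed`.
#' @examples
#' ch <- simulate_cohort(correlation_spec(), seed = 1)
#' round(cor(ch$values[, "Y"], ch$values[, "X"]), 2)
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "correlation_spec"))
  R <- build_correlation_matrix(spec)
  k <- ncol(R)
  L <- chol(R)
  vals <- with_seed(seed, {
    matrix(stats::rnorm(spec$n * k), spec$n, k) %*% L
  })
  colnames(vals) <- colnames(R)
  structure(list(values = vals, seed = as.integer(seed)), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d x %d (seed %d)\n", nrow(x$values), ncol(x$values), x$seed
  ))
  invisible(x)
}

#' Squared coefficient of multiple correlation with the outcome
#'
#' For a predictor subset of the data model, the proportion of outcome
#' variance explained by the best linear predictor. Because the non-outcome
#' variables are mutually uncorrelated, this is exactly the sum of squared
#' outcome correlations over the subset -- a closed form, not a simulation.
#' It is the natural scalar measure of how much auxiliary information an
#' imputation model carries.
#'
#' @param spec A [correlation_spec()].
#' @param predictors Character vector of predictor labels (subset of the
#'   spec's variable names, e.g. `c("X", "Z1")`).
#' @return A value in `[0, 1]`.
#' @examples
#' multiple_r2(correlation_spec(), "X") # 0.36
#' @export
multiple_r2 <- function(spec, predictors) {
  stopifnot(inherits(spec, "correlation_spec"))
  if (length(predictors) == 0L) {
    warning("empty predictor set carries no information; R^2 = 0")
    return(0)
  }
  predictors <- as.character(predictors)
  unknown <- setdiff(predictors, names(spec$outcome_correlations))
  if (length(unknown)) {
    stop("unknown predictors: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(predictors)) stop("duplicated predictors")
  sum(spec$outcome_correlations[predictors]^2)
}

#' Write / read a cohort as plain CSV
#'
#' The CSV has a header row `Y,X,Z1,...`; masked outcome values (when
#' writing a [masked_cohort]) are empty cells.
#'
#' @param x A `cohort` or `masked_cohort`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort` (no missing cells) or `masked_cohort` (empty `Y`
#'   cells become the missingness mask).
#' @export
write_cohort_csv <- function(x, path) {
  vals <- x$values
  utils::write.csv(as.data.frame(vals), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  vals <- as.matrix(df)
  if (colnames(vals)[1L] != "Y") stop("first column must be the outcome Y")
  mask <- is.na(vals[, "Y"])
  if (any(is.na(vals[, -1L]))) stop("missing values are only supported in Y")
  if (any(mask)) {
    structure(
      list(values = vals, missing_mask = mask),
      class = "masked_cohort"
    )
  } else {
    structure(list(values = vals, seed = NA_integer_), class = "cohort")
  }
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed derivation: fold integer components into [0, 2^31 - 2]
# with a Lehmer-style mix. Keeps every (replicate, stage, model) stream
# reproducible in isolation and independent of execution order.
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (x in list(...)) {
    if (is.character(x)) x <- sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
    h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h)
}
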