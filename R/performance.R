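#' Monte-Carlo bias of an estimator
#'
#' Mean estimate minus the true value, with its Monte-Carlo standard error
#' `sd(estimates) / sqrt(n_sim)`.
#'
#' @param estimates Numeric vector of per-replicate point estimates.
#' @param truth True parameter value.
#' @return A list with `bias` and `mcse`.
#' @export
bias <- function(estimates, truth) {
  stopifnot(length(estimates) >= 2L)
  list(
    bias = mean(estimates) - truth,
    mcse = stats::sd(estimates) / sqrt(length(estimates))
  )
}

#' Empirical standard error of an estimator
#'
#' Sample standard deviation of the per-replicate estimates (divisor
#' `n_sim - 1`), with the normal-theory Monte-Carlo standard error
#' `emp_se / sqrt(2 (n_sim - 1))`.
#'
#' @param estimates Numeric vector of per-replicate point estimates.
#' @return A list with `emp_se` and `mcse`.
#' @export
empirical_se <- function(estimates) {
  stopifnot(length(estimates) >= 2L)
  s <- stats::sd(estimates)
  list(emp_se = s, mcse = s / sqrt(2 * (length(estimates) - 1)))
}

#' Median and interquartile range of per-replicate FMI values
#'
#' Quantiles use linear interpolation (R's default type-7 rule); any fixed
#' rule would do at the replicate counts used here, but the rule is pinned
#' for reproducibility.
#'
#' @param fmis Numeric vector of FMI values.
#' @return A list with `median` and `iqr` (`Q3 - Q1`).
#' @export
summarize_fmi <- function(fmis) {
  stopifnot(length(fmis) >= 1L)
  q <- stats::quantile(fmis, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], iqr = q[3L] - q[1L])
}

#' Percentage reduction in empirical SE relative to complete case analysis
#'
#' `100 * (se_cca - se_mi) / se_cca`. Positive values mean the MI estimate
#' is more precise than the complete case estimate.
#'
#' @param se_cca,se_mi Empirical standard errors of the CCA and MI
#'   estimators.
#' @return Percentage reduction.
#' @export
pct_se_reduction <- function(se_cca, se_mi) {
  if (any(se_cca <= 0)) stop("se_cca must be positive")
  100 * (se_cca - se_mi) / se_cca
}

#' Percentage reduction in absolute bias relative to complete case analysis
#'
#' `100 * (|bias_cca| - |bias_mi|) / |bias_cca|`. Can be negative when MI
#' is more biased than CCA. Undefined when the CCA bias is exactly zero;
#' that case returns `NA` with a warning.
#'
#' @param bias_cca,bias_mi Biases of the CCA and MI estimators.
#' @return Percentage reduction in absolute bias.
#' @export
pct_bias_reduction <- function(bias_cca, bias_mi) {
  out <- 100 * (abs(bias_cca) - abs(bias_mi)) / abs(bias_cca)
  if (any(bias_cca == 0)) {
    warning("bias_cca is zero; percentage bias reduction is undefined")
    out[bias_cca == 0] <- NA_real_
  }
  out
}

#' Summarise replicate-level study results into a performance table
#'
#' Takes the tidy replicate-level results of [run_study()] and produces one
#' row per (mechanism, proportion, model, coefficient) with the
#' Monte-Carlo performance measures: bias and empirical SE with their
#' MCSEs, the median and IQR of the FMI, and -- for MI models -- the
#' percentage reductions in empirical SE and absolute bias relative to the
#' paired complete case analysis of the same simulated datasets.
#'
#' @param replicates Tibble of replicate-level records (see [run_study()]).
#' @param truth Named vector of true coefficient values.
#' @return A tibble, one row per scenario cell and coefficient.
#' @export
summarize_study <- function(replicates, truth = c(b0 = 0, b1 = 0.6)) {
  stopifnot(all(c("mechanism", "p", "model", "replicate", "term", "estimate") %in%
                  names(replicates)))
  truth_tbl <- tibble::tibble(term = names(truth), truth = unname(truth))
  summ <- replicates |>
    dplyr::left_join(truth_tbl, by = "term") |>
    dplyr::group_by(.data$mechanism, .data$p, .data$model, .data$term) |>
    dplyr::summarise(
      n_sim = dplyr::n(),
      bias = mean(.data$estimate) - .data$truth[1L],
      bias_mcse = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      emp_se = stats::sd(.data$estimate),
      emp_se_mcse = stats::sd(.data$estimate) / sqrt(2 * (dplyr::n() - 1)),
      fmi_median = if (all(is.na(.data$fmi))) NA_real_ else
        stats::quantile(.data$fmi, 0.5, names = FALSE, type = 7),
      fmi_iqr = if (all(is.na(.data$fmi))) NA_real_ else
        diff(stats::quantile(.data$fmi, c(0.25, 0.75), names = FALSE, type = 7)),
      .groups = "drop"
    )
  cca <- summ |>
    dplyr::filter(.data$model == "CCA") |>
    dplyr::select("mechanism", "p", "term",
                  cca_bias = "bias", cca_emp_se = "emp_se")
  summ |>
    dplyr::left_join(cca, by = c("mechanism", "p", "term")) |>
    dplyr::mutate(
      pct_se_reduction = dplyr::if_else(
        .data$model == "CCA", NA_real_,
        pct_se_reduction(.data$cca_emp_se, .data$emp_se)
      ),
      pct_bias_reduction = dplyr::if_else(
        .data$model == "CCA" | .data$cca_bias == 0, NA_real_,
        100 * (abs(.data$cca_bias) - abs(.data$bias)) / abs(.data$cca_bias)
      )
    ) |>
    dplyr::select(-"cca_bias", -"cca_emp_se") |>
    dplyr::arrange(.data$mechanism, .data$p, .data$model, .data$term)
}

#' Reshape a performance summary into the wide reduction table
#'
#' One row per (proportion, model) with the percentage SE reduction under
#' MCAR and MAR and the percentage bias reduction under MAR for the
#' exposure coefficient -- the layout used to compare MI models against
#' complete case analysis.
#'
#' @param summary A [summarize_study()] result covering both mechanisms.
#' @return A wide tibble.
#' @export
reduction_table <- function(summary) {
  summary |>
    dplyr::filter(.data$term == "b1", .data$model != "CCA") |>
    dplyr::transmute(
      .data$p, .data$model, .data$mechanism,
      se_red = .data$pct_se_reduction, bias_red = .data$pct_bias_reduction
    ) |>
    tidyr::pivot_wider(
      names_from = "mechanism",
      values_from = c("se_red", "bias_red")
    ) |>
    dplyr::arrange(.data$p, .data$model)
}
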