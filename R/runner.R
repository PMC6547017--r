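#' Configuration of a full simulation study
#'
#' Bundles everything needed to reproduce a study: the data-model spec, the
#' scenario grid (mechanisms x missingness proportions x imputation
#' models), the Monte-Carlo sizes and a single master seed from which every
#' replicate's cohort, mask and imputation seeds are derived.
#'
#' @param master_seed Master RNG seed; all per-replicate seeds derive from
#'   it deterministically.
#' @param n_sim Number of simulated datasets per scenario cell.
#' @param n Cohort size.
#' @param m Number of imputations per imputation model.
#' @param proportions Missingness proportions, each in `(0, 1)`.
#' @param mechanisms Subset of `c("MCAR", "MAR")`.
#' @param models Either a character subset of the standard model labels
#'   (`"model 1"` .. `"model 5"`) or a list of [imputation_model()] specs.
#' @param spec A [correlation_spec()] for the data model.
#' @param mar_coef_z1,mar_coef_x MAR selection-model coefficients.
#' @return A `study_config` object.
#' @export
study_config <- function(master_seed = 1L,
                         n_sim = 1000L,
                         n = 1000L,
                         m = 1000L,
                         proportions = c(0.01, 0.05, 0.10, 0.20, 0.40, 0.60, 0.80, 0.90),
                         mechanisms = c("MCAR", "MAR"),
                         models = paste("model", 1:5),
                         spec = NULL,
                         mar_coef_z1 = 1,
                         mar_coef_x = 1) {
  n_sim <- as.integer(n_sim)
  n <- as.integer(n)
  m <- as.integer(m)
  stopifnot(n_sim >= 1L, n >= 3L, m >= 2L)
  if (any(proportions <= 0 | proportions >= 1)) {
    stop("all missingness proportions must lie strictly in (0, 1)")
  }
  mechanisms <- match.arg(mechanisms, c("MCAR", "MAR"), several.ok = TRUE)
  if (is.character(models)) {
    models <- default_imputation_models(m = m, labels = models)
  } else {
    stopifnot(all(vapply(models, inherits, logical(1L), "imputation_model_spec")))
    models <- lapply(models, function(mod) imputation_model(mod$label, mod$predictors, m = m))
    names(models) <- vapply(models, `[[`, character(1L), "label")
  }
  if (is.null(spec)) spec <- correlation_spec(n = n) else spec$n <- n
  structure(
    list(
      master_seed = as.integer(master_seed), n_sim = n_sim, n = n, m = m,
      proportions = proportions, mechanisms = mechanisms, models = models,
      spec = spec, mar_coef_z1 = mar_coef_z1, mar_coef_x = mar_coef_x
    ),
    class = "study_config"
  )
}

#' A reduced-scale preset of the full study grid
#'
#' Same scenario grid as the defaults but with `n_sim = 200` replicates and
#' `m = 200` imputations per cell, sized so a laptop can re-run the whole
#' grid; Monte-Carlo standard errors are wider by a factor of about
#' `sqrt(5)` relative to the full-scale study.
#'
#' @param master_seed Master RNG seed.
#' @param ... Further arguments passed to [study_config()].
#' @return A `study_config`.
#' @export
reduced_study_config <- function(master_seed = 1L, ...) {
  study_config(master_seed = master_seed, n_sim = 200L, m = 200L, ...)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> n_sim = %d, n = %d, m = %d, seed = %d\n  mechanisms: %s\n  proportions: %s\n  models: %s\n",
    x$n_sim, x$n, x$m, x$master_seed,
    paste(x$mechanisms, collapse = ", "),
    paste(format(x$proportions), collapse = ", "),
    paste(names(x$models), collapse = ", ")
  ))
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' The config file is a flat key-value document holding the master seed,
#' Monte-Carlo sizes, proportions, mechanisms, model predictor sets, the
#' outcome-correlation vector and the MAR coefficients, so a study is fully
#' reproducible from the file alone.
#'
#' @param path File path.
#' @param config A `study_config`.
#' @return `read_study_config` returns a `study_config`;
#'   `write_study_config` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  # the cohort size lives under `n_obs`: a bare `n` key is a YAML 1.1
  # boolean, though a quoted 'n' still works and is accepted here
  y$n_obs <- y$n_obs %||% y$n
  models <- if (is.null(y$models)) {
    paste("model", 1:5)
  } else if (is.character(y$models)) {
    y$models
  } else {
    lapply(names(y$models), function(lbl) {
      imputation_model(lbl, y$models[[lbl]], m = round(y$m %||% 1000L))
    })
  }
  spec <- if (is.null(y$outcome_correlations)) NULL else {
    correlation_spec(unlist(y$outcome_correlations), n = y$n_obs %||% 1000L)
  }
  study_config(
    master_seed = y$master_seed %||% 1L,
    n_sim = y$n_sim %||% 1000L,
    n = y$n_obs %||% 1000L,
    m = y$m %||% 1000L,
    proportions = unlist(y$proportions %||% c(0.01, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 0.9)),
    mechanisms = unlist(y$mechanisms %||% c("MCAR", "MAR")),
    models = models,
    spec = spec,
    mar_coef_z1 = y$mar_coef_z1 %||% 1,
    mar_coef_x = y$mar_coef_x %||% 1
  )
}

#' @rdname read_study_config
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  y <- list(
    master_seed = config$master_seed,
    n_sim = config$n_sim, n_obs = config$n, m = config$m,
    proportions = config$proportions,
    mechanisms = config$mechanisms,
    models = lapply(config$models, `[[`, "predictors"),
    outcome_correlations = as.list(config$spec$outcome_correlations),
    mar_coef_z1 = config$mar_coef_z1,
    mar_coef_x = config$mar_coef_x
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one scenario cell of a simulation study
#'
#' Simulates `n_sim` cohorts, imposes the given missingness mechanism at
#' proportion `p`, runs the complete case analysis and every requested MI
#' model on each cohort (all analyses of a replicate share the same masked
#' dataset, so comparisons are paired), and returns tidy replicate-level
#' records. Cohort seeds depend only on (master seed, replicate), so cells
#' at different `p` or mechanism reuse the same underlying cohorts --
#' comparisons across cells are paired too.
#'
#' @param config A [study_config()].
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param p Missingness proportion.
#' @param verbose Log per-cell progress to stderr.
#' @return A tibble with columns `mechanism`, `p`, `model`, `replicate`,
#'   `term`, `estimate`, `se`, `fmi`, `df`, `cohort_seed`, `mask_seed`,
#'   `imputation_seed` (`NA` where not applicable).
#' @export
run_cell <- function(config, mechanism, p, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  t0 <- proc.time()[["elapsed"]]
  scenario <- if (mechanism == "MAR") {
    missingness_scenario("MAR", p,
      coef_z1 = config$mar_coef_z1, coef_x = config$mar_coef_x
    )
  } else {
    missingness_scenario("MCAR", p)
  }
  models <- config$models
  out <- vector("list", config$n_sim)
  for (i in seq_len(config$n_sim)) {
    cohort_seed <- derive_seed(config$master_seed, 1L, i)
    mask_seed <- derive_seed(config$master_seed, 2L, i, mechanism, round(p * 1e6))
    cohort <- simulate_cohort(config$spec, cohort_seed)
    masked <- if (mechanism == "MCAR") {
      apply_mcar(cohort, p)
    } else {
      apply_mar(cohort, scenario, mask_seed)
    }
    cca <- fit_analysis_model(masked, complete_rows_only = TRUE)
    recs <- list(tibble::tibble(
      model = "CCA", replicate = i, term = c("b0", "b1"),
      estimate = unname(cca$coefficients),
      se = sqrt(unname(cca$variances)),
      fmi = NA_real_, df = NA_real_,
      cohort_seed = cohort_seed, mask_seed = mask_seed,
      imputation_seed = NA_integer_
    ))
    for (mod in models) {
      imp_seed <- derive_seed(
        config$master_seed, 3L, i, mechanism, round(p * 1e6), mod$label
      )
      pooled <- pool_rubin(analyse_stack(impute_stack(masked, mod, imp_seed)))
      recs[[length(recs) + 1L]] <- tibble::tibble(
        model = mod$label, replicate = i, term = pooled$term,
        estimate = pooled$estimate, se = pooled$se,
        fmi = pooled$fmi_adjusted, df = pooled$df,
        cohort_seed = cohort_seed, mask_seed = mask_seed,
        imputation_seed = imp_seed
      )
    }
    out[[i]] <- dplyr::bind_rows(recs)
  }
  res <- dplyr::bind_rows(out) |>
    dplyr::mutate(mechanism = mechanism, p = p, .before = 1L)
  if (verbose) {
    message(sprintf(
      "[fmisim] %s p=%.2f: %d replicates x %d models in %.1fs",
      mechanism, p, config$n_sim, length(models),
      proc.time()[["elapsed"]] - t0
    ))
  }
  res
}

#' Run a full simulation study
#'
#' Executes every (mechanism, proportion) cell of the config and summarises
#' the replicate-level results into a performance table. Cells are
#' independent: a failure in one cell is logged and the remaining cells
#' still run. The whole study is reproducible from the config alone; the
#' replicate records carry the derived seeds, so any single number in the
#' output can be recomputed in isolation.
#'
#' @param config A [study_config()].
#' @param verbose Log per-cell timing to stderr.
#' @return A list with `replicates` (tidy per-replicate records),
#'   `summary` (the [summarize_study()] performance table) and `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  grid <- expand.grid(
    p = config$proportions, mechanism = config$mechanisms,
    stringsAsFactors = FALSE
  )
  cells <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cells[[g]] <- tryCatch(
      run_cell(config, grid$mechanism[g], grid$p[g], verbose = verbose),
      error = function(e) {
        message(sprintf(
          "[fmisim] cell %s p=%.2f failed: %s",
          grid$mechanism[g], grid$p[g], conditionMessage(e)
        ))
        NULL
      }
    )
  }
  replicates <- dplyr::bind_rows(cells)
  truth <- c(b0 = 0, b1 = unname(config$spec$outcome_correlations["X"]))
  list(
    replicates = replicates,
    summary = summarize_study(replicates, truth = truth),
    config = config
  )
}
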