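#!/usr/bin/env Rscript

# Thin command-line front end over the fmisim package.
#
#   Rscript scripts/misim.R simulate --n 1000 --seed 1 --out cohort.csv
#   Rscript scripts/misim.R run --config study.yaml --out-dir results/
#   Rscript scripts/misim.R reductions --summary results/summary.csv --out table.csv

suppressPackageStartupMessages(library(fmisim))

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: misim.R <simulate|run|reductions> [options]", call. = FALSE)
}
cmd <- args[1L]
opts <- list()
i <- 2L
while (i < length(args) + 1L && startsWith(args[i], "--")) {
  opts[[sub("^--", "", args[i])]] <- args[i + 1L]
  i <- i + 2L
}

if (cmd == "simulate") {
  n <- as.integer(opts$n %||% 1000L)
  seed <- as.integer(opts$seed %||% 1L)
  out <- opts$out %||% "cohort.csv"
  cohort <- simulate_cohort(correlation_spec(n = n), seed)
  if (!is.null(opts$mcar)) cohort <- apply_mcar(cohort, as.numeric(opts$mcar))
  write_cohort_csv(cohort, out)
  message(sprintf("wrote %s (n = %d, seed = %d)", out, n, seed))
} else if (cmd == "run") {
  if (is.null(opts$config)) stop("run needs --config <yaml>")
  out_dir <- opts[["out-dir"]] %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- read_study_config(opts$config)
  print(config)
  res <- run_study(config, verbose = TRUE)
  utils::write.csv(res$replicates, file.path(out_dir, "replicates.csv"), row.names = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  message(sprintf("wrote %s/{replicates,summary}.csv", out_dir))
} else if (cmd == "reductions") {
  if (is.null(opts$summary)) stop("reductions needs --summary <csv>")
  summ <- utils::read.csv(opts$summary)
  wide <- reduction_table(tibble::as_tibble(summ))
  out <- opts$out %||% stdout()
  utils::write.csv(as.data.frame(wide), out, row.names = FALSE)
} else {
  stop("unknown subcommand: ", cmd)
}
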