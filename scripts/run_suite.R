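#!/usr/bin/env Rscript
# Thin command-line wrapper over the package's experiment suites.
#
# Usage:
#   Rscript scripts/run_suite.R --suite fig6a_composition --outdir out
#   Rscript scripts/run_suite.R --suite all --outdir out --seed 2
#   Rscript scripts/run_suite.R --validate
#   Rscript scripts/run_suite.R --config my_params.yaml --validate

suppressPackageStartupMessages({
  library(optparse)
  library(nfcrosstalk)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--suite", type = "character", default = NULL,
              help = "suite name or 'all'"),
  make_option("--outdir", type = "character", default = "suite_output"),
  make_option("--seed", type = "integer", default = 1),
  make_option("--n-cells", type = "integer", default = 25, dest = "n_cells"),
  make_option("--cv", type = "double", default = 0.15),
  make_option("--config", type = "character", default = NULL,
              help = "optional parameter config (YAML/JSON)"),
  make_option("--validate", action = "store_true", default = FALSE,
              help = "run the calibration constraint report and exit")
)))

params <- if (is.null(opts$config)) build_parameters() else
  build_parameters(opts$config)

status <- 0
if (opts$validate) {
  rep <- validate_calibration(params)
  print(rep, n = Inf)
  if (!all(rep$pass)) status <- 1
} else if (is.null(opts$suite)) {
  message("nothing to do: pass --suite <name|all> or --validate")
  status <- 2
} else {
  suites <- c("fig6a_composition", "fig6b_trajectories", "fig7d_genotypes",
              "fig8_resensitization")
  run <- if (identical(opts$suite, "all")) suites else opts$suite
  for (s in run) {
    res <- run_scenario_suite(s, outdir = opts$outdir, seed = opts$seed,
                              n_cells = opts$n_cells, cv = opts$cv,
                              params = params)
    message("wrote ", paste(res$manifest$outputs, collapse = ", "))
  }
}
quit(status = status)
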