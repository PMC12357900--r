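# End-to-end in-silico experiment suites: steady-state inhibitor
# compositions, CD40 ensembles, genotype fold changes, and BH3-mimetic
# resensitization, each written as tidy CSV with a reproducibility manifest.

#' Validate the calibration constraints of a parameter set
#'
#' Evaluates the qualitative constraint surface the canonical parameters are
#' calibrated to: (C1) higher steady-state nuclear RelA at high basal
#' activation; (C2) >2-fold RelB:p52 induction by 24 h CD40 at both basal
#' levels; (C3) nuclear RelA within +/-20% under CD40; (C4) >=1.5-fold
#' nuclear cRel induction only at high basal (<1.1-fold at low); (C5)
#' IkB-alpha + IkB-epsilon hold <=14% of the inhibitor-bound cRel pool at
#' the high-basal steady state; (C6) the affinity-ordering constraints.
#'
#' @param params An `nfkb_params` object or path to a parameter config file.
#' @return Tibble: `constraint`, `description`, `value`, `bound`, `pass`.
#' @export
validate_calibration <- function(params = build_parameters()) {
  if (is.character(params)) params <- build_parameters(params)
  lo <- apply_basal_activation(params, 0.0005)
  hi <- apply_basal_activation(params, 0.005)
  ss_lo <- nfkb_steady_state(lo)
  ss_hi <- nfkb_steady_state(hi)
  cd40 <- stimulus_spec(cd40_on = TRUE)
  tr_lo <- simulate_nfkb(lo, ss_lo, 1440, cd40, label = "low_basal_CD40")
  tr_hi <- simulate_nfkb(hi, ss_hi, 1440, cd40, label = "high_basal_CD40")
  fold <- function(tr, sp) {
    tr[[sp]][nrow(tr)] / tr[[sp]][1]
  }
  comp <- inhibitor_composition(ss_hi, "C")
  rows <- list(
    list("C1", "nuclear RelA higher at high basal",
         unname(ss_hi["A_nuc"] / ss_lo["A_nuc"]), "> 1",
         ss_hi[["A_nuc"]] > ss_lo[["A_nuc"]]),
    list("C2a", "RelB:p52 induction > 2-fold (low basal)",
         fold(tr_lo, "B_nuc"), "> 2", fold(tr_lo, "B_nuc") > 2),
    list("C2b", "RelB:p52 induction > 2-fold (high basal)",
         fold(tr_hi, "B_nuc"), "> 2", fold(tr_hi, "B_nuc") > 2),
    list("C3a", "nuclear RelA within +/-20% under CD40 (low basal)",
         fold(tr_lo, "A_nuc"), "[0.8, 1.2]",
         fold(tr_lo, "A_nuc") >= 0.8 && fold(tr_lo, "A_nuc") <= 1.2),
    list("C3b", "nuclear RelA within +/-20% under CD40 (high basal)",
         fold(tr_hi, "A_nuc"), "[0.8, 1.2]",
         fold(tr_hi, "A_nuc") >= 0.8 && fold(tr_hi, "A_nuc") <= 1.2),
    list("C4a", "nuclear cRel induction < 1.1-fold at low basal",
         fold(tr_lo, "C_nuc"), "< 1.1", fold(tr_lo, "C_nuc") < 1.1),
    list("C4b", "nuclear cRel induction >= 1.5-fold at high basal",
         fold(tr_hi, "C_nuc"), ">= 1.5", fold(tr_hi, "C_nuc") >= 1.5),
    list("C5", "IkBa+IkBe fraction of bound cRel at high basal",
         comp$f_IkBa + comp$f_IkBe, "<= 0.14",
         comp$f_IkBa + comp$f_IkBe <= 0.14),
    list("C6a", "IkBd binds cRel more tightly than RelA",
         params$kb_Id_C / params$kb_Id_A, "> 1",
         params$kb_Id_C > params$kb_Id_A),
    list("C6b", "IkBa binds RelA more tightly than cRel",
         params$kb_Ia_A / params$kb_Ia_C, "> 1",
         params$kb_Ia_A > params$kb_Ia_C)
  )
  purrr::map(rows, function(r) {
    tibble::tibble(constraint = r[[1]], description = r[[2]],
                   value = r[[3]], bound = r[[4]], pass = r[[5]])
  }) |> dplyr::bind_rows()
}

#' Run a named in-silico experiment suite
#'
#' Executes one of the shipped suites and (optionally) writes its tidy CSV
#' outputs plus a JSON run manifest:
#' \describe{
#'   \item{fig6a_composition}{steady-state inhibitor composition of RelA:p50
#'     and cRel:p50 at low and high basal activation}
#'   \item{fig6b_trajectories}{25-cell CD40 ensembles at both basal levels,
#'     with per-species mean/sd summaries}
#'   \item{fig7d_genotypes}{WT / IkBe-KO / IkBa-kBkB ensemble fold changes
#'     of steady-state nuclear RelA and cRel}
#'   \item{fig8_resensitization}{LC50 triples (mono / co-culture /
#'     co-culture + modulator) for the shipped cell-line x drug panel}
#' }
#'
#' @param suite Suite name (see above).
#' @param outdir Output directory; `NULL` returns results without writing.
#' @param seed Integer seed for all stochastic stages.
#' @param n_cells Ensemble size (default 25).
#' @param cv Parameter-jitter log-sd (default 0.15).
#' @param params Base `nfkb_params`.
#' @return List with `suite`, `results` (named tibbles) and `manifest`.
#' @export
run_scenario_suite <- function(suite, outdir = NULL, seed = 1, n_cells = 25,
                               cv = 0.15, params = build_parameters()) {
  suites <- c("fig6a_composition", "fig6b_trajectories", "fig7d_genotypes",
              "fig8_resensitization")
  if (!suite %in% suites) {
    stop("unknown suite '", suite, "'; available: ",
         paste(suites, collapse = ", "), call. = FALSE)
  }
  results <- switch(
    suite,
    fig6a_composition = .suite_composition(params),
    fig6b_trajectories = .suite_trajectories(params, n_cells, cv, seed),
    fig7d_genotypes = .suite_genotypes(params, n_cells, cv, seed),
    fig8_resensitization = .suite_resensitization(params)
  )
  manifest <- list(
    suite = suite,
    seed = seed,
    n_cells = n_cells,
    cv = cv,
    config_hash = rlang::hash(list(suite, seed, n_cells, cv,
                                   unclass(params))),
    version = as.character(utils::packageVersion("nfcrosstalk")),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = character(0)
  )
  if (!is.null(outdir)) {
    dir.create(file.path(outdir, suite), recursive = TRUE,
               showWarnings = FALSE)
    for (nm in names(results)) {
      p <- file.path(outdir, suite, paste0(nm, ".csv"))
      utils::write.csv(results[[nm]], p, row.names = FALSE)
      manifest$outputs <- c(manifest$outputs, p)
    }
    jsonlite::write_json(manifest,
                         file.path(outdir, suite, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(suite = suite, results = results, manifest = manifest)
}

.suite_composition <- function(params) {
  rows <- purrr::map(c(low = 0.0005, high = 0.005), function(b) {
    ss <- nfkb_steady_state(apply_basal_activation(params, b))
    dplyr::bind_rows(inhibitor_composition(ss, "A"),
                     inhibitor_composition(ss, "C")) |>
      dplyr::mutate(basal = b, .before = 1)
  })
  list(composition = dplyr::bind_rows(rows))
}

.suite_trajectories <- function(params, n_cells, cv, seed) {
  cd40 <- stimulus_spec(cd40_on = TRUE)
  out <- purrr::imap(c(low_basal = 0.0005, high_basal = 0.005),
                     function(b, nm) {
    cells <- sample_cells(apply_basal_activation(params, b), n = n_cells,
                          cv = cv, seed = seed + (b == 0.005))
    run_ensemble(cells, cd40, duration = 1440,
                 label = paste0(nm, "_CD40"))
  })
  list(
    trajectories = dplyr::bind_rows(purrr::map(out, tidy_ensemble)),
    summary = dplyr::bind_rows(purrr::imap(out, function(e, nm) {
      dplyr::mutate(summarize_ensemble(e), scenario = e$label)
    }))
  )
}

.suite_genotypes <- function(params, n_cells, cv, seed) {
  base <- apply_basal_activation(params, 0.0005)
  ens <- purrr::imap(
    list(WT = "WT", IkBe_KO = "IkBe_KO", IkBa_kBkB = "IkBa_kBkB"),
    function(g, nm) {
      offset <- match(nm, c("WT", "IkBe_KO", "IkBa_kBkB")) - 1
      cells <- sample_cells(apply_genotype(base, g), n = n_cells, cv = cv,
                            seed = seed + 101 * offset)
      run_ensemble(cells, stimulus_spec(), duration = 60, n_points = 5,
                   label = nm)
    })
  folds <- purrr::map(c(RelA = "A_nuc_t0", cRel = "C_nuc_t0"),
                      function(ro) {
    purrr::imap(ens[c("IkBe_KO", "IkBa_kBkB")], function(e, nm) {
      fc <- fold_change(e, ens$WT, readout = ro)
      tibble::tibble(genotype = nm, mean = attr(fc, "mean"),
                     sd = attr(fc, "sd"), n = attr(fc, "n"))
    }) |> dplyr::bind_rows()
  })
  list(fold_changes = dplyr::bind_rows(folds, .id = "readout"))
}

.suite_resensitization <- function(params) {
  nik <- list(type = "NIK_inh", dose = 50, Ki = 5)
  btk <- list(type = "BTK_inh", dose = 0.1, Ki = 0.01)
  azd <- list(type = "drug", name = "AZD5991", dose = 0.01)
  panel <- list(
    list("RIVA", "ABT199", nik),
    list("U2932", "ABT199", nik),
    list("SUDHL8", "A1331852", btk),
    list("SUDHL8", "A1331852", azd),
    list("SUDHL8", "A1331852", nik)
  )
  rows <- purrr::map(panel, function(pl) {
    r <- resensitization_experiment(pl[[1]], pl[[2]], pl[[3]],
                                    params = params)
    mod <- if (pl[[3]]$type == "drug") pl[[3]]$name else pl[[3]]$type
    dplyr::mutate(tibble::as_tibble(r), cell_line = pl[[1]],
                  drug = pl[[2]], modulator = mod, .before = 1)
  })
  list(lc50 = dplyr::bind_rows(rows))
}
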