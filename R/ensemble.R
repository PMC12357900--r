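# Virtual-cell ensembles: parameter-sampled populations emulating
# cell-to-cell heterogeneity in protein expression. Only synthesis and
# degradation rates are jittered (expression heterogeneity); binding
# affinities are treated as biophysical constants shared across cells.

.sampled_rates <- c(
  "k_syn_A", "k_syn_C", "k_syn_RelB", "k_syn_NIK",
  "k_deg_A", "k_deg_C", "k_deg_B", "k_deg_NIK",
  "k0_Ia", "k0_Ie", "k0_Id", "g_Ia", "g_Ie", "g_Id",
  "d0_Ia", "d0_Ie", "d0_Id", "d_ikk_Ia", "d_ikk_Ie", "k_proc"
)

#' Names of the rates jittered across virtual cells
#' @return Character vector of parameter names.
#' @export
sampled_rate_names <- function() .sampled_rates

#' Sample a virtual-cell population
#'
#' Each cell multiplies every synthesis and degradation rate of `base` by an
#' independent log-normal factor with median 1 and log-sd `cv`. Affinities
#' and the basal-activation fraction are shared. Deterministic given `seed`.
#'
#' @param base An `nfkb_params` object.
#' @param n Number of cells (>= 1); 25 is the standard ensemble size.
#' @param cv Log-scale standard deviation of the jitter (>= 0, default 0.15).
#' @param seed Integer seed.
#' @param rates Which parameters to jitter (default [sampled_rate_names()]).
#' @return List of `n` `nfkb_params` objects, names `cell_01` ...
#' @export
sample_cells <- function(base, n = 25, cv = 0.15, seed = 1,
                         rates = sampled_rate_names()) {
  stopifnot(n >= 1, cv >= 0)
  base <- validate_parameters(base, strict_b = FALSE)
  factors <- .with_seed(seed, matrix(
    stats::rlnorm(n * length(rates), meanlog = 0, sdlog = cv),
    nrow = n))
  cells <- lapply(seq_len(n), function(i) {
    p <- base
    if (cv > 0) {
      for (j in seq_along(rates)) {
        p[[rates[j]]] <- p[[rates[j]]] * factors[i, j]
      }
    }
    validate_parameters(p, strict_b = FALSE)
  })
  names(cells) <- sprintf("cell_%02d", seq_len(n))
  cells
}

#' Run a scenario over a virtual-cell ensemble
#'
#' Simulates each cell from its own unstimulated steady state under the given
#' stimulus, on a common output time grid. Integration failures are collected
#' per cell, never silently dropped.
#'
#' @param cells List of `nfkb_params` (from [sample_cells()]).
#' @param stimulus A `stimulus_spec`.
#' @param duration Minutes (default 1440).
#' @param n_points Output grid size.
#' @param label Scenario label.
#' @param from_steady Start each cell from its unstimulated steady state
#'   (default TRUE); otherwise from the all-zero state.
#' @return An `nfkb_ensemble`: list with `trajectories` (tibble: cell_id,
#'   time, species columns), `cells`, `label`, `errors`.
#' @export
run_ensemble <- function(cells, stimulus = stimulus_spec(), duration = 1440,
                         n_points = 97, label = "ensemble",
                         from_steady = TRUE) {
  stopifnot(length(cells) >= 1)
  errors <- list()
  trajs <- purrr::imap(cells, function(p, id) {
    tryCatch({
      init <- if (from_steady) nfkb_steady_state(p) else zero_state()
      tr <- simulate_nfkb(p, init, duration = duration, stimulus = stimulus,
                          n_points = n_points, label = label)
      tr$cell_id <- id
      tr
    }, error = function(e) {
      errors[[id]] <<- conditionMessage(e)
      NULL
    })
  })
  if (length(errors)) {
    stop("integration failed for ", length(errors), " cell(s): ",
         paste(names(errors), collapse = ", "), " [first: ",
         errors[[1]], "]", call. = FALSE)
  }
  out <- list(
    trajectories = dplyr::bind_rows(trajs),
    cells = cells,
    label = label,
    n = length(cells)
  )
  class(out) <- "nfkb_ensemble"
  out
}

#' @export
print.nfkb_ensemble <- function(x, ...) {
  cat("<nfkb_ensemble>", x$label, "-", x$n, "cells,",
      dplyr::n_distinct(x$trajectories$time), "time points\n")
  invisible(x)
}

#' Ensemble mean and standard deviation per species and time
#'
#' @param ensemble An `nfkb_ensemble`.
#' @return Tibble: `time`, `species`, `mean`, `sd`, `n`.
#' @export
summarize_ensemble <- function(ensemble) {
  ensemble$trajectories |>
    tidyr::pivot_longer(dplyr::all_of(species_names()),
                        names_to = "species", values_to = "value") |>
    dplyr::group_by(.data$time, .data$species) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Per-cell scalar readout of an ensemble
#'
#' Extracts one number per cell: `"<species>_end"` (endpoint value),
#' `"<species>_t0"` (initial value) or `"<species>_fold"` (endpoint/initial).
#'
#' @param ensemble An `nfkb_ensemble`.
#' @param readout Readout string, e.g. `"C_nuc_fold"`.
#' @return Tibble: `cell_id`, `value`.
#' @export
ensemble_readout <- function(ensemble, readout) {
  m <- regmatches(readout, regexec("^(.*)_(end|t0|fold)$", readout))[[1]]
  if (length(m) != 3 || !(m[2] %in% species_names())) {
    stop("readout must be '<species>_end', '<species>_t0' or '<species>_fold' ",
         "with a valid species name, got '", readout, "'", call. = FALSE)
  }
  sp <- m[2]; what <- m[3]
  ensemble$trajectories |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      value = switch(what,
        end = .data[[sp]][which.max(.data$time)],
        t0 = .data[[sp]][which.min(.data$time)],
        fold = .data[[sp]][which.max(.data$time)] /
               .data[[sp]][which.min(.data$time)]),
      .groups = "drop")
}

#' Fold change of an ensemble readout relative to a reference ensemble
#'
#' Per-cell fold = readout(perturbed cell) / mean(readout over the reference
#' ensemble). The reference mean (not cell pairing) is used because perturbed
#' and reference populations are unpaired.
#'
#' @param perturbed,reference `nfkb_ensemble` objects with equal cell count
#'   and time grid.
#' @param readout String `"<species>_end"`, `"<species>_t0"` or
#'   `"<species>_fold"`, e.g. `"C_nuc_end"` for endpoint nuclear cRel.
#' @return A tibble of class `fold_change_summary`: `readout`, `cell_id`,
#'   `fold`, plus attributes `mean`, `sd`, `n`.
#' @export
fold_change <- function(perturbed, reference, readout = "C_nuc_end") {
  stopifnot(inherits(perturbed, "nfkb_ensemble"),
            inherits(reference, "nfkb_ensemble"))
  if (perturbed$n != reference$n) {
    stop("ensembles must have the same number of cells", call. = FALSE)
  }
  tp <- sort(unique(perturbed$trajectories$time))
  tr <- sort(unique(reference$trajectories$time))
  if (length(tp) != length(tr) || max(abs(tp - tr)) > 1e-9) {
    stop("ensembles must share the output time grid", call. = FALSE)
  }
  pv <- ensemble_readout(perturbed, readout)
  rv <- ensemble_readout(reference, readout)
  ref_mean <- mean(rv$value)
  if (!is.finite(ref_mean) || ref_mean == 0) {
    stop("reference readout mean is zero; fold change undefined", call. = FALSE)
  }
  out <- tibble::tibble(readout = readout, cell_id = pv$cell_id,
                        fold = pv$value / ref_mean)
  attr(out, "mean") <- mean(out$fold)
  attr(out, "sd") <- stats::sd(out$fold)
  attr(out, "n") <- nrow(out)
  class(out) <- c("fold_change_summary", class(out))
  out
}

#' Tidy export of an ensemble (long format)
#'
#' @param ensemble An `nfkb_ensemble`.
#' @return Tibble: `cell_id`, `time`, `species`, `value`, `scenario`.
#' @export
tidy_ensemble <- function(ensemble) {
  ensemble$trajectories |>
    tidyr::pivot_longer(dplyr::all_of(species_names()),
                        names_to = "species", values_to = "value") |>
    dplyr::select("cell_id", "time", "species", "value", "scenario")
}
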