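# Synthetic-data generators with planted ground truth. Every generator is
# deterministic given its seed and returns (or writes) a machine-readable
# truth sidecar, so downstream estimators can be tested end-to-end without
# any external data. Intensity-like quantities are log-normal, the standard
# model for cytometry channels.

#' Specification for a synthetic flow-cytometry sample
#'
#' Describes a (possibly multi-clonal) stained sample plus its matched
#' unstained control. Populations are mixtures over markers: each population
#' carries a per-marker log10-median and log10-sd.
#'
#' @param populations List of populations; each a list with `weight` and
#'   `markers`, the latter a named list of `c(log10_median, log10_sd)` pairs.
#'   Weights must sum to 1.
#' @param n Number of cells (>= 1).
#' @param unstained_log10_median,unstained_log10_sd Autofluorescence floor of
#'   the unstained control, shared across markers.
#' @param seed Integer seed.
#' @return List of class `flow_spec`.
#' @examples
#' spec <- flow_spec(list(list(weight = 1,
#'   markers = list(RelA = c(3, 0.2), RelB = c(2.5, 0.2)))), n = 100)
#' @export
flow_spec <- function(populations, n = 5000, unstained_log10_median = 2,
                      unstained_log10_sd = 0.15, seed = 1) {
  stopifnot(n >= 1, length(populations) >= 1)
  w <- vapply(populations, function(p) p$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    stop("population weights must sum to 1", call. = FALSE)
  }
  sds <- unlist(lapply(populations, function(p)
    vapply(p$markers, function(m) m[2], numeric(1))))
  if (any(sds <= 0)) stop("log10-sds must be positive", call. = FALSE)
  structure(list(populations = populations, n = n,
                 unstained_log10_median = unstained_log10_median,
                 unstained_log10_sd = unstained_log10_sd, seed = seed),
            class = "flow_spec")
}

#' Generate a synthetic stained/unstained flow sample pair
#'
#' Cells are assigned to populations by the mixture weights; each marker
#' value is drawn log-normally (base-10 parameters) from its population.
#' The unstained control shares the autofluorescence floor across markers.
#'
#' @param spec A [flow_spec()].
#' @param sample_name Sample label used in the output tables.
#' @return List: `stained` and `unstained` (tibbles: sample, cell_id,
#'   population, marker, value) and `truth` (planted medians and weights).
#' @export
gen_flow_sample <- function(spec, sample_name = "synthetic") {
  stopifnot(inherits(spec, "flow_spec"))
  markers <- names(spec$populations[[1]]$markers)
  .with_seed(spec$seed, {
    w <- vapply(spec$populations, function(p) p$weight, numeric(1))
    pop <- sample.int(length(w), spec$n, replace = TRUE, prob = w)
    stained <- purrr::map(markers, function(mk) {
      mu <- vapply(spec$populations, function(p) p$markers[[mk]][1],
                   numeric(1))
      sd <- vapply(spec$populations, function(p) p$markers[[mk]][2],
                   numeric(1))
      tibble::tibble(
        sample = sample_name,
        cell_id = seq_len(spec$n),
        population = pop,
        marker = mk,
        value = 10^stats::rnorm(spec$n, mu[pop], sd[pop]))
    }) |> dplyr::bind_rows()
    unstained <- purrr::map(markers, function(mk) {
      tibble::tibble(
        sample = paste0(sample_name, "_unstained"),
        cell_id = seq_len(spec$n),
        population = NA_integer_,
        marker = mk,
        value = 10^stats::rnorm(spec$n, spec$unstained_log10_median,
                                spec$unstained_log10_sd))
    }) |> dplyr::bind_rows()
    truth <- list(
      weights = w,
      medians = purrr::map(spec$populations, function(p)
        vapply(p$markers, function(m) 10^m[1], numeric(1))),
      unstained_median = 10^spec$unstained_log10_median,
      seed = spec$seed)
    list(stained = stained, unstained = unstained, truth = truth)
  })
}

#' Specification for a synthetic dose-response experiment
#'
#' @param bottom,top,slope,lc50 True 4PL parameters (`lc50` > 0).
#' @param doses Ascending positive dose grid (uM).
#' @param replicates Replicates per dose (>= 1).
#' @param noise_sd Gaussian noise sd added to viability.
#' @param seed Integer seed.
#' @return List of class `dose_response_spec`.
#' @export
dose_response_spec <- function(bottom = 0.05, top = 1, slope = 2,
                               lc50 = 0.1, doses = default_doses(),
                               replicates = 3, noise_sd = 0.05, seed = 1) {
  stopifnot(lc50 > 0, all(doses > 0), !is.unsorted(doses), replicates >= 1,
            noise_sd >= 0, bottom <= top)
  structure(list(bottom = bottom, top = top, slope = slope, lc50 = lc50,
                 doses = doses, replicates = replicates, noise_sd = noise_sd,
                 seed = seed),
            class = "dose_response_spec")
}

#' Generate a synthetic viability table from a known 4PL curve
#'
#' Viability = 4PL(dose) + N(0, noise_sd), clipped to [0, 1.05] to mimic
#' assay noise above 100%.
#'
#' @param spec A [dose_response_spec()].
#' @return List: `data` (tibble: dose, replicate, viability) and `truth`
#'   (the 4PL parameters, incl. `lc50`).
#' @export
gen_dose_response <- function(spec) {
  stopifnot(inherits(spec, "dose_response_spec"))
  .with_seed(spec$seed, {
    grid <- tidyr::expand_grid(dose = spec$doses,
                               replicate = seq_len(spec$replicates))
    mu <- spec$bottom + (spec$top - spec$bottom) /
      (1 + (grid$dose / spec$lc50)^spec$slope)
    v <- mu + stats::rnorm(nrow(grid), 0, spec$noise_sd)
    grid$viability <- pmin(pmax(v, 0), 1.05)
    list(data = grid,
         truth = list(bottom = spec$bottom, top = spec$top,
                      slope = spec$slope, lc50 = spec$lc50,
                      seed = spec$seed))
  })
}

#' Generate synthetic per-cell nuclear:cytoplasmic ratio tables
#'
#' One log-normal population per row of `populations`, with an optional
#' planted multiplicative shift (e.g. a co-culture effect).
#'
#' @param populations Tibble (or data frame) with columns `sample`,
#'   `median` (> 0), `log_sd` (natural-log sd, > 0) and optionally `shift`
#'   (multiplicative, default 1).
#' @param n Cells per population.
#' @param seed Integer seed.
#' @return List: `data` (tibble: sample, cell_id, ratio) and `truth`
#'   (planted shifted medians).
#' @export
gen_nc_ratios <- function(populations, n = 2000, seed = 1) {
  stopifnot(all(c("sample", "median", "log_sd") %in% names(populations)),
            all(populations$median > 0), all(populations$log_sd > 0))
  if (!"shift" %in% names(populations)) populations$shift <- 1
  .with_seed(seed, {
    data <- purrr::pmap(populations, function(sample, median, log_sd,
                                              shift, ...) {
      tibble::tibble(sample = sample, cell_id = seq_len(n),
                     ratio = stats::rlnorm(n, log(median * shift), log_sd))
    }) |> dplyr::bind_rows()
    truth <- tibble::tibble(sample = populations$sample,
                            true_median = populations$median *
                              populations$shift)
    list(data = data, truth = truth)
  })
}

#' Generate a synthetic ChIP peak table around a TSS
#'
#' Places `n_in` peaks overlapping the +/- `half_window` bp window around
#' the TSS and `n_out` peaks outside it, with log-normal scores, and plants
#' `n_outliers` in-window peaks whose scores sit at least
#' `outlier_sd` robust-SDs above the bulk.
#'
#' @param n_in,n_out,n_outliers Peak counts (>= 0); outliers count towards
#'   `n_in`.
#' @param tss_position TSS coordinate (0-based).
#' @param half_window Window half-width (bp).
#' @param score_meanlog,score_sdlog Log-normal score parameters of the bulk.
#' @param outlier_sd Planted outlier distance in robust-SD units (>= 6 for
#'   the documented recovery guarantees).
#' @param subunits Subunit labels sampled uniformly per peak.
#' @param seed Integer seed.
#' @return List: `peaks` (tibble: chrom, start, end, score, subunit,
#'   dataset, planted_in_window, planted_outlier), `tss` (one-row tibble),
#'   `truth`.
#' @export
gen_chip_peaks <- function(n_in = 20, n_out = 30, n_outliers = 0,
                           tss_position = 100000, half_window = 1000,
                           score_meanlog = 4, score_sdlog = 0.4,
                           outlier_sd = 6.5,
                           subunits = c("RelA", "RelB", "cRel"), seed = 1) {
  stopifnot(n_in >= 0, n_out >= 0, n_outliers <= n_in)
  .with_seed(seed, {
    width <- 200
    mk <- function(k, inside) {
      if (k == 0) return(NULL)
      if (inside) {
        start <- round(stats::runif(k, tss_position - half_window,
                                    tss_position + half_window))
      } else {
        off <- sample(c(-1, 1), k, replace = TRUE) *
          round(stats::runif(k, half_window + width + 10,
                             half_window + 50000))
        start <- tss_position + off
      }
      tibble::tibble(chrom = "chr1", start = start, end = start + width,
                     score = stats::rlnorm(k, score_meanlog, score_sdlog),
                     subunit = sample(subunits, k, replace = TRUE),
                     dataset = sprintf("ds%02d", sample.int(5, k, TRUE)),
                     planted_in_window = inside,
                     planted_outlier = FALSE)
    }
    proto <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), score = numeric(),
                            subunit = character(), dataset = character(),
                            planted_in_window = logical(),
                            planted_outlier = logical())
    peaks <- dplyr::bind_rows(proto, mk(n_in, TRUE), mk(n_out, FALSE))
    if (n_outliers > 0) {
      idx <- which(peaks$planted_in_window)[seq_len(n_outliers)]
      bulk <- peaks$score[peaks$planted_in_window][-seq_len(n_outliers)]
      center <- stats::median(peaks$score)
      rsd <- stats::quantile(abs(peaks$score - center), 0.6827,
                             names = FALSE)
      peaks$score[idx] <- center + outlier_sd * rsd *
        stats::runif(n_outliers, 1, 1.5)
      peaks$planted_outlier[idx] <- TRUE
    }
    tss <- tibble::tibble(gene = "MCL1", chrom = "chr1",
                          position = tss_position, strand = "+")
    list(peaks = peaks, tss = tss,
         truth = list(n_in_window = n_in, n_out = n_out,
                      outlier_scores = peaks$score[peaks$planted_outlier],
                      seed = seed))
  })
}

#' Write a generator result with its JSON truth sidecar
#'
#' Writes each tabular element of a generator result as CSV and the `truth`
#' element as JSON, into `dir`.
#'
#' @param result A list returned by a `gen_*` function.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_synthetic <- function(result, dir, prefix = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(result)) {
    el <- result[[nm]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
      utils::write.csv(el, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (!is.null(result$truth)) {
    p <- file.path(dir, paste0(prefix, "_truth.json"))
    jsonlite::write_json(result$truth, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
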