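# BCL2-family induction and BH3-mimetic viability. The viability model is a
# deliberate minimal surrogate: anti-apoptotic proteins provide additive
# sequestration capacity for the cell's pro-apoptotic load, a BH3 mimetic
# removes its target's contribution occupancy-wise, and a cell dies when the
# remaining capacity falls below its (log-normally distributed) requirement.
# No mitochondrial kinetics, no Bax/Bak dynamics.

#' Transcription weights linking nuclear NF-kB dimers to BCL2-family genes
#'
#' Per-gene basal synthesis plus Hill-saturating contributions from nuclear
#' RelA:p50 (`A`), RelB:p52 (`B`) and cRel:p50 (`C`). RelB dominates BCLXL
#' (with small promiscuous weights from all dimers), cRel dominates MCL1, and
#' BCL2 is constitutive (no NF-kB weight). Cell-line presets differ only in
#' basal rates: "RIVA" and "U2932" are BCL2-high, "U2932_R1" additionally
#' MCL1-high (the venetoclax-resistant subclone), "SUDHL8" BCL2-low.
#'
#' @param cell_line One of `"generic"`, `"RIVA"`, `"U2932"`, `"U2932_R1"`,
#'   `"U2932_R2"`, `"SUDHL8"`.
#' @return A list of class `bcl2_weights`; one element per gene with fields
#'   `basal` (a.u./min), `w` (named dimer weights, a.u./min at saturation),
#'   `K` (Hill half-max, nuclear a.u.), `h` (Hill coefficient), `half_life`
#'   (protein half-life, min).
#' @export
bcl2_weights <- function(cell_line = "generic") {
  cell_line <- match.arg(cell_line, c("generic", "RIVA", "U2932", "U2932_R1",
                                      "U2932_R2", "SUDHL8"))
  basal <- switch(cell_line,
    generic = c(BCL2 = 0.10, BCLXL = 0.10, MCL1 = 0.10),
    RIVA = c(BCL2 = 0.30, BCLXL = 0.05, MCL1 = 0.10),
    U2932 = , U2932_R2 = c(BCL2 = 0.30, BCLXL = 0.05, MCL1 = 0.10),
    U2932_R1 = c(BCL2 = 0.30, BCLXL = 0.05, MCL1 = 0.60),
    SUDHL8 = c(BCL2 = 0.03, BCLXL = 0.10, MCL1 = 0.10))
  w <- list(
    BCL2 = list(basal = basal[["BCL2"]],
                w = c(A = 0, B = 0, C = 0), K = 2, h = 2, half_life = 240),
    BCLXL = list(basal = basal[["BCLXL"]],
                 w = c(A = 0.05, B = 0.8, C = 0.05), K = 2, h = 2,
                 half_life = 240),
    MCL1 = list(basal = basal[["MCL1"]],
                w = c(A = 0.05, B = 0, C = 0.6), K = 3, h = 4,
                half_life = 240)
  )
  structure(w, class = "bcl2_weights", cell_line = cell_line)
}

# transcription rate of one gene given nuclear dimer levels (vectorized in time)
.bcl2_rate <- function(gene, A, B, C) {
  hill <- function(x, K, h) x^h / (K^h + x^h)
  gene$basal + gene$w[["A"]] * hill(A, gene$K, gene$h) +
    gene$w[["B"]] * hill(B, gene$K, gene$h) +
    gene$w[["C"]] * hill(C, gene$K, gene$h)
}

#' Induce BCL2-family proteins along an NF-kB trajectory
#'
#' Each protein obeys dX/dt = rate(t) - (ln 2 / half-life) X with rate(t)
#' from [bcl2_weights()] applied to the trajectory's nuclear dimer levels.
#' The initial abundance is the steady state of the trajectory's first time
#' point, so the fold change of a flat (unstimulated) trajectory is 1.
#'
#' @param trajectory An `nfkb_trajectory`.
#' @param weights A `bcl2_weights` object.
#' @return Tibble of class `bcl2_profile`: `gene`, `baseline`, `abundance`
#'   (endpoint), `fold`.
#' @export
induce_bcl2_family <- function(trajectory, weights = bcl2_weights()) {
  stopifnot(inherits(weights, "bcl2_weights"))
  tt <- trajectory$time
  A <- trajectory$A_nuc; B <- trajectory$B_nuc; C <- trajectory$C_nuc
  purrr::imap(weights, function(gene, name) {
    k <- log(2) / gene$half_life
    r <- .bcl2_rate(gene, A, B, C)
    x <- numeric(length(tt))
    x[1] <- r[1] / k
    # exact update for piecewise-linear rate approximated by interval midpoint
    for (i in seq_along(tt)[-1]) {
      dt <- tt[i] - tt[i - 1]
      rm_ <- (r[i] + r[i - 1]) / 2
      x[i] <- rm_ / k + (x[i - 1] - rm_ / k) * exp(-k * dt)
    }
    tibble::tibble(gene = name, baseline = x[1], abundance = x[length(x)],
                   fold = x[length(x)] / x[1])
  }) |>
    dplyr::bind_rows() |>
    structure(class = c("bcl2_profile", class(tibble::tibble())))
}

#' BH3-mimetic drug specification
#'
#' @param name `"ABT199"` (targets BCL2), `"A1331852"` (BCLXL) or
#'   `"AZD5991"` (MCL1).
#' @param Ki On-target half-inhibition constant (uM, default 0.01).
#' @param specificity Fold-selectivity: off-target proteins are engaged with
#'   `Ki * specificity` (default 1000), reflecting the loss of BH3-mimetic
#'   specificity at high dose.
#' @return List of class `drug_spec` with fields `name`, `target`, `Ki`,
#'   `specificity`.
#' @export
drug_spec <- function(name, Ki = 0.01, specificity = 1000) {
  name <- match.arg(name, c("ABT199", "A1331852", "AZD5991"))
  stopifnot(Ki > 0, specificity >= 1)
  target <- c(ABT199 = "BCL2", A1331852 = "BCLXL", AZD5991 = "MCL1")[[name]]
  structure(list(name = name, target = target, Ki = Ki,
                 specificity = specificity), class = "drug_spec")
}

#' Per-protein pro-apoptotic dependence weights
#'
#' How much of the cell's pro-apoptotic load each anti-apoptotic protein
#' sequesters (the line's "dependence"). BCL2-driven lines weight BCL2
#' highest; SUDHL8-like lines weight BCLXL highest with substantial MCL1.
#'
#' @param cell_line As in [bcl2_weights()].
#' @return Named numeric vector over BCL2, BCLXL, MCL1.
#' @export
dependence_profile <- function(cell_line = "generic") {
  cell_line <- match.arg(cell_line, c("generic", "RIVA", "U2932", "U2932_R1",
                                      "U2932_R2", "SUDHL8"))
  switch(cell_line,
    generic = c(BCL2 = 1, BCLXL = 1, MCL1 = 1),
    RIVA = , U2932 = , U2932_R1 = , U2932_R2 =
      c(BCL2 = 1, BCLXL = 0.35, MCL1 = 0.35),
    SUDHL8 = c(BCL2 = 0.35, BCLXL = 1, MCL1 = 0.6))
}

#' Viability of a BCL2-family profile under a BH3 mimetic
#'
#' Effective anti-apoptotic capacity
#' `E(dose) = sum_X dep_X * abundance_X / (1 + dose / Ki_X(dose))`, with the
#' drug's on-target Ki for its target and `Ki * specificity` off-target. A
#' cell survives if `E` exceeds its apoptotic threshold, log-normally
#' distributed across the population, so
#' `viability = plnorm(E, log(threshold_median), threshold_spread)`.
#' Monotone non-increasing in dose.
#'
#' @param profile A `bcl2_profile` (or tibble with `gene`, `abundance`).
#' @param drug A `drug_spec`.
#' @param doses Ascending non-negative doses (uM).
#' @param dependence Named per-protein dependence weights.
#' @param threshold_median Median capacity requirement (a.u., default 100).
#' @param threshold_spread Log-sd of the threshold distribution (default 0.3).
#' @param codrug Optional second `drug_spec` applied at fixed dose
#'   `codrug_dose` (on-target only), e.g. sub-lethal MCL1 inhibition.
#' @param codrug_dose Dose of the co-drug (uM).
#' @return Tibble of class `viability_curve`: `dose`, `capacity`, `viability`.
#' @export
viability_curve <- function(profile, drug, doses,
                            dependence = c(BCL2 = 1, BCLXL = 1, MCL1 = 1),
                            threshold_median = 100, threshold_spread = 0.3,
                            codrug = NULL, codrug_dose = 0) {
  if (!length(doses)) stop("dose list is empty", call. = FALSE)
  if (any(doses < 0) || is.unsorted(doses)) {
    stop("doses must be non-negative and ascending", call. = FALSE)
  }
  stopifnot(inherits(drug, "drug_spec"))
  ab <- stats::setNames(profile$abundance, profile$gene)
  genes <- names(ab)
  if (!is.null(codrug)) {
    stopifnot(inherits(codrug, "drug_spec"), codrug_dose >= 0)
    ab[[codrug$target]] <- ab[[codrug$target]] /
      (1 + codrug_dose / codrug$Ki)
  }
  capacity <- vapply(doses, function(d) {
    sum(vapply(genes, function(g) {
      Ki_eff <- if (g == drug$target) drug$Ki else drug$Ki * drug$specificity
      dependence[[g]] * ab[[g]] / (1 + d / Ki_eff)
    }, numeric(1)))
  }, numeric(1))
  viability <- stats::plnorm(capacity, meanlog = log(threshold_median),
                             sdlog = threshold_spread)
  structure(tibble::tibble(dose = doses, capacity = capacity,
                           viability = viability),
            class = c("viability_curve", class(tibble::tibble())),
            drug = drug$name)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d / lc50)^slope)` on log dose,
#' with multi-start Levenberg-Marquardt initialization. The LC50 is the
#' inflection dose; it is flagged `extrapolated` when outside the fitted dose
#' span and the fit is flagged `degenerate` for flat responses.
#'
#' @param doses Positive doses (>= 4 distinct values).
#' @param viability Viability values (same length; replicates allowed by
#'   repeating doses).
#' @return Object of class `fourpl_fit`: list with `bottom`, `top`, `slope`,
#'   `lc50`, `residual_norm`, `converged`, `degenerate`, `extrapolated`,
#'   `n`, `data`.
#' @examples
#' d <- 10^seq(-3, 1, length.out = 9)
#' v <- 0.05 + 0.9 / (1 + (d / 0.1)^1.2)
#' fit_4pl(d, v)$lc50
#' @export
fit_4pl <- function(doses, viability) {
  ok <- is.finite(doses) & is.finite(viability) & doses > 0
  doses <- doses[ok]; viability <- viability[ok]
  if (length(unique(doses)) < 4) {
    stop("need >= 4 distinct positive doses", call. = FALSE)
  }
  rng <- range(viability)
  out <- list(bottom = NA_real_, top = NA_real_, slope = NA_real_,
              lc50 = NA_real_, residual_norm = NA_real_, converged = FALSE,
              degenerate = FALSE, extrapolated = FALSE,
              n = length(doses),
              data = tibble::tibble(dose = doses, viability = viability))
  if (diff(rng) < 0.05) {
    out$degenerate <- TRUE
    class(out) <- "fourpl_fit"
    return(out)
  }
  ld <- log10(doses)
  df <- data.frame(ld = ld, v = viability)
  # dose nearest the half-response as LC50 seed
  mid <- (max(viability) + min(viability)) / 2
  seed_l50 <- ld[which.min(abs(viability - mid))]
  starts <- expand.grid(slope = c(0.5, 1, 2),
                        l50 = unique(c(seed_l50, stats::median(ld))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^((ld - l50) * slope)),
        data = df,
        start = list(bottom = 0, top = 1,
                     slope = starts$slope[i], l50 = starts$l50[i]),
        lower = c(-0.5, 0, 0.01, min(ld) - 6),
        upper = c(1, 1.6, 20, max(ld) + 6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from any start", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  if (cf[["bottom"]] > cf[["top"]]) {   # enforce bottom <= top orientation
    tmp <- cf[["bottom"]]; cf[["bottom"]] <- cf[["top"]]; cf[["top"]] <- tmp
  }
  out$bottom <- unname(cf[["bottom"]])
  out$top <- unname(cf[["top"]])
  out$slope <- unname(cf[["slope"]])
  out$lc50 <- 10^unname(cf[["l50"]])
  out$residual_norm <- sqrt(best$rss)
  out$converged <- TRUE
  out$extrapolated <- out$lc50 < min(doses) || out$lc50 > max(doses)
  class(out) <- "fourpl_fit"
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<fourpl_fit> degenerate (flat response), LC50 undefined\n")
  } else {
    cat(sprintf(
      "<fourpl_fit> LC50 = %.4g%s, slope = %.2f, range [%.3f, %.3f]\n",
      x$lc50, if (x$extrapolated) " (extrapolated)" else "",
      x$slope, x$bottom, x$top))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL fit
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(term = c("bottom", "top", "slope", "lc50"),
                 estimate = c(x$bottom, x$top, x$slope, x$lc50))
}

#' One-row fit summary
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return Tibble with `lc50`, `residual_norm`, `converged`, `degenerate`,
#'   `extrapolated`, `n`.
#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(lc50 = x$lc50, residual_norm = x$residual_norm,
                 converged = x$converged, degenerate = x$degenerate,
                 extrapolated = x$extrapolated, n = x$n)
}

#' Default dose grid for BH3-mimetic assays
#'
#' Thirteen log-spaced doses over 0.0001-100 uM.
#' @return Numeric vector of doses (uM).
#' @export
default_doses <- function() 10^seq(-4, 2, length.out = 13)

#' In-silico BH3-mimetic resensitization experiment
#'
#' Runs the full pipeline for one cell line and drug under three conditions -
#' monoculture, CD40L co-culture, and co-culture plus a modulator - and
#' returns the fitted LC50 triple. Each condition simulates the NF-kB model
#' (24 h from the line's steady state), induces the BCL2-family profile, and
#' fits a 4PL to the viability curve.
#'
#' @param cell_line `"RIVA"`, `"U2932"`, `"U2932_R1"`, or `"SUDHL8"`.
#' @param drug A `drug_spec` or drug name.
#' @param modulator Optional modulator for the third condition: either
#'   `list(type = "NIK_inh", dose, Ki)`, `list(type = "BTK_inh", dose, Ki)`,
#'   or `list(type = "drug", name, dose)` for a sub-lethal BH3-mimetic
#'   co-drug.
#' @param doses Dose grid (uM).
#' @param params Base `nfkb_params`.
#' @param ... Passed to [viability_curve()].
#' @return Tibble of class `resensitization_result`: `condition`, `lc50`,
#'   `extrapolated`, `degenerate`; fitted objects in `attr(, "fits")`.
#' @export
resensitization_experiment <- function(cell_line, drug, modulator = NULL,
                                       doses = default_doses(),
                                       params = build_parameters(), ...) {
  cell_line <- match.arg(cell_line, c("RIVA", "U2932", "U2932_R1", "SUDHL8"))
  if (is.character(drug)) drug <- drug_spec(drug)
  basal <- if (cell_line == "SUDHL8") 0.005 else 0.0005
  p <- apply_basal_activation(params, basal)
  weights <- bcl2_weights(cell_line)
  dep <- dependence_profile(cell_line)

  conditions <- list(
    mono = list(stim = stimulus_spec(cd40_on = FALSE), codrug = NULL, cd = 0),
    co_culture = list(stim = stimulus_spec(cd40_on = TRUE), codrug = NULL,
                      cd = 0)
  )
  if (!is.null(modulator)) {
    stim3 <- stimulus_spec(cd40_on = TRUE)
    codrug <- NULL; cd <- 0
    if (modulator$type %in% c("NIK_inh", "BTK_inh")) {
      stim3 <- apply_inhibitor(stim3, modulator$type, modulator$dose,
                               modulator$Ki)
    } else if (modulator$type == "drug") {
      codrug <- drug_spec(modulator$name)
      cd <- modulator$dose
    } else {
      stop("unknown modulator type: ", modulator$type, call. = FALSE)
    }
    conditions$co_culture_modulated <-
      list(stim = stim3, codrug = codrug, cd = cd)
  }

  ss <- nfkb_steady_state(p)
  fits <- purrr::imap(conditions, function(cond, nm) {
    tr <- simulate_nfkb(p, ss, duration = 1440, stimulus = cond$stim,
                        label = paste(cell_line, nm, sep = "_"))
    prof <- induce_bcl2_family(tr, weights)
    vc <- viability_curve(prof, drug, doses, dependence = dep,
                          codrug = cond$codrug, codrug_dose = cond$cd, ...)
    fit_4pl(vc$dose, vc$viability)
  })
  out <- tibble::tibble(
    condition = names(fits),
    lc50 = purrr::map_dbl(fits, "lc50"),
    extrapolated = purrr::map_lgl(fits, "extrapolated"),
    degenerate = purrr::map_lgl(fits, "degenerate"))
  attr(out, "fits") <- fits
  attr(out, "cell_line") <- cell_line
  attr(out, "drug") <- drug$name
  class(out) <- c("resensitization_result", class(out))
  out
}
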