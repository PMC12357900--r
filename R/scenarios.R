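#' Construct a stimulus specification
#'
#' A stimulus bundles the time-dependent inputs of a simulation: CD40
#' ligation (which stabilizes NIK by slowing its degradation), pharmacological
#' inhibitor factors, and an optional additive B-cell-receptor pulse on IKK.
#'
#' @param cd40_on Logical; is CD40L stimulation present?
#' @param cd40_start Onset time of CD40 ligation (min, >= 0).
#' @param btk_inhibitor_factor Multiplicative factor in (0, 1] applied to the
#'   basal (BCR/BTK-driven) IKK activity.
#' @param nik_inhibitor_factor Multiplicative factor in (0, 1] applied to the
#'   NIK-dependent processing rate.
#' @param bcr_pulse Optional function of time returning an additive IKK term
#'   (as a multiple of basal activity), or a single number; default 0.
#' @return A list of class `stimulus_spec`.
#' @examples
#' stimulus_spec(cd40_on = TRUE)
#' @export
stimulus_spec <- function(cd40_on = FALSE, cd40_start = 0,
                          btk_inhibitor_factor = 1,
                          nik_inhibitor_factor = 1,
                          bcr_pulse = NULL) {
  stopifnot(is.logical(cd40_on), length(cd40_on) == 1)
  if (!is.numeric(cd40_start) || cd40_start < 0) {
    stop("cd40_start must be >= 0", call. = FALSE)
  }
  for (f in c(btk_inhibitor_factor, nik_inhibitor_factor)) {
    if (!is.numeric(f) || f <= 0 || f > 1) {
      stop("inhibitor factors must lie in (0, 1]", call. = FALSE)
    }
  }
  if (!is.null(bcr_pulse) && !is.function(bcr_pulse) &&
      !(is.numeric(bcr_pulse) && length(bcr_pulse) == 1)) {
    stop("bcr_pulse must be NULL, a number, or a function of time",
         call. = FALSE)
  }
  structure(
    list(cd40_on = cd40_on, cd40_start = cd40_start,
         btk_inhibitor_factor = btk_inhibitor_factor,
         nik_inhibitor_factor = nik_inhibitor_factor,
         bcr_pulse = bcr_pulse),
    class = "stimulus_spec"
  )
}

#' CD40-driven NIK degradation multiplier
#'
#' CD40 ligation stabilizes NIK; the degradation rate is scaled by
#' `1 / (1 + t/600)` with `t` the time (minutes) since CD40 onset, so the
#' multiplier is 1 at onset, 0.5 at 600 min, and decays towards 0.
#'
#' @param t_since_onset Time since CD40 onset in minutes (vectorized, >= 0).
#' @return Multiplier(s) in (0, 1].
#' @examples
#' cd40_multiplier(c(0, 600, 1800))
#' @export
cd40_multiplier <- function(t_since_onset) {
  if (any(t_since_onset < 0)) stop("t_since_onset must be >= 0", call. = FALSE)
  1 / (1 + t_since_onset / 600)
}

# effective NIK degradation multiplier at absolute time t under a stimulus
.nik_deg_multiplier <- function(t, stimulus) {
  if (isTRUE(stimulus$cd40_on) && t >= stimulus$cd40_start) {
    cd40_multiplier(t - stimulus$cd40_start)
  } else {
    1
  }
}

#' Set the basal canonical activation fraction
#'
#' Returns a copy of `params` with the basal (BCR-driven) IKK activity
#' fraction `b` replaced. The modeled range is 0 to 0.5% (0 to 0.005);
#' larger values are accepted with a warning for sensitivity analysis.
#'
#' @param params An `nfkb_params` object.
#' @param fraction New basal activation fraction (>= 0).
#' @return A new `nfkb_params` object; the input is not modified.
#' @export
apply_basal_activation <- function(params, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction < 0) {
    stop("fraction must be a single number >= 0", call. = FALSE)
  }
  params$b <- fraction
  validate_parameters(params, strict_b = FALSE)
}

#' Apply a B-cell genotype to a parameter set
#'
#' Genotypes scale inhibitor synthesis: `IkBe_KO` abolishes IkB-epsilon
#' synthesis; `IkBa_kBkB` (a kB-site promoter mutation) reduces IkB-alpha
#' synthesis by `ikba_factor`; `WT` is the identity.
#'
#' @param params An `nfkb_params` object.
#' @param genotype One of `"WT"`, `"IkBe_KO"`, `"IkBa_kBkB"`.
#' @param ikba_factor Synthesis multiplier used by `IkBa_kBkB` (default 0.5).
#' @return A new `nfkb_params` object.
#' @export
apply_genotype <- function(params, genotype, ikba_factor = 0.5) {
  genotype <- match.arg(genotype, c("WT", "IkBe_KO", "IkBa_kBkB"))
  if (genotype == "IkBe_KO") {
    params$k0_Ie <- 0
    params$g_Ie <- 0
  } else if (genotype == "IkBa_kBkB") {
    params$k0_Ia <- params$k0_Ia * ikba_factor
    params$g_Ia <- params$g_Ia * ikba_factor
  }
  validate_parameters(params, strict_b = FALSE)
}

#' Apply a pharmacological NF-kB inhibitor to a stimulus
#'
#' A simple occupancy model: the targeted activity is scaled by
#' `1 / (1 + dose/Ki)`. `NIK_inh` (e.g. Amgen16) scales NIK-dependent
#' processing; `BTK_inh` (e.g. ibrutinib) scales the basal canonical IKK
#' activity. Factors compose multiplicatively with any already present.
#'
#' @param stimulus A `stimulus_spec`.
#' @param drug `"NIK_inh"` or `"BTK_inh"`.
#' @param dose Drug dose (> 0, same units as `Ki`).
#' @param Ki Half-inhibition constant (> 0).
#' @return A new `stimulus_spec`.
#' @export
apply_inhibitor <- function(stimulus, drug, dose, Ki) {
  drug <- match.arg(drug, c("NIK_inh", "BTK_inh"))
  if (!is.numeric(dose) || dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (!is.numeric(Ki) || Ki <= 0) stop("Ki must be > 0", call. = FALSE)
  factor <- 1 / (1 + dose / Ki)
  if (drug == "NIK_inh") {
    stimulus$nik_inhibitor_factor <- stimulus$nik_inhibitor_factor * factor
  } else {
    stimulus$btk_inhibitor_factor <- stimulus$btk_inhibitor_factor * factor
  }
  stimulus
}

#' Named scenario presets
#'
#' Returns the parameter set and stimulus for the shipped cell-line-like
#' scenarios. "RIVA-like" cells carry low basal canonical activation
#' (b = 0.0005) and "SUDHL8-like" cells high basal activation (b = 0.005),
#' the endpoints of the modeled 0-0.5% range; "U2932-like" behaves like RIVA
#' at the signaling level (its distinguishing feature, high BCL2, lives in
#' the BCL2-family layer). Inhibitor presets use the documented default doses
#' and Ki values.
#'
#' @param name One of `"RIVA_mono"`, `"RIVA_CD40"`, `"RIVA_CD40_amgen16"`,
#'   `"U2932_mono"`, `"U2932_CD40"`, `"U2932_CD40_amgen16"`, `"SUDHL8_mono"`,
#'   `"SUDHL8_CD40"`, `"SUDHL8_CD40_ibrutinib"`, `"SUDHL8_CD40_amgen16"`,
#'   `"WT"`, `"IkBe_KO"`, `"IkBa_kBkB"`.
#' @param params Optional base parameter set (defaults to the canonical set).
#' @return List with elements `params` (`nfkb_params`), `stimulus`
#'   (`stimulus_spec`) and `label`.
#' @export
scenario_preset <- function(name, params = build_parameters()) {
  choices <- c("RIVA_mono", "RIVA_CD40", "RIVA_CD40_amgen16",
               "U2932_mono", "U2932_CD40", "U2932_CD40_amgen16",
               "SUDHL8_mono", "SUDHL8_CD40", "SUDHL8_CD40_ibrutinib",
               "SUDHL8_CD40_amgen16", "WT", "IkBe_KO", "IkBa_kBkB")
  name <- match.arg(name, choices)
  low <- 0.0005
  high <- 0.005
  base <- switch(
    name,
    RIVA_mono = , RIVA_CD40 = , RIVA_CD40_amgen16 = ,
    U2932_mono = , U2932_CD40 = , U2932_CD40_amgen16 =
      apply_basal_activation(params, low),
    SUDHL8_mono = , SUDHL8_CD40 = , SUDHL8_CD40_ibrutinib = ,
    SUDHL8_CD40_amgen16 = apply_basal_activation(params, high),
    WT = apply_genotype(params, "WT"),
    IkBe_KO = apply_genotype(params, "IkBe_KO"),
    IkBa_kBkB = apply_genotype(params, "IkBa_kBkB")
  )
  stim <- stimulus_spec(cd40_on = grepl("CD40", name))
  # documented inhibitor defaults: Amgen16 50 uM (Ki 5 uM), ibrutinib 0.1 uM
  # (Ki 0.01 uM) - strong but incomplete target engagement
  if (grepl("amgen16", name)) {
    stim <- apply_inhibitor(stim, "NIK_inh", dose = 50, Ki = 5)
  }
  if (grepl("ibrutinib", name)) {
    stim <- apply_inhibitor(stim, "BTK_inh", dose = 0.1, Ki = 0.01)
  }
  list(params = base, stimulus = stim, label = name)
}
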