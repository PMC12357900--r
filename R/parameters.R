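#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
"_PACKAGE"

# Species ordering used throughout the ODE right-hand side. Positional access
# keeps the derivative evaluation cheap inside the integrator.
.species <- c(
  "A_cyt", "A_nuc",       # free RelA:p50, cytoplasmic / nuclear
  "C_cyt", "C_nuc",       # free cRel:p50
  "IkBa", "IkBe", "P100", # free inhibitors; P100 carries the IkB-delta activity
  "IkBa_A", "IkBe_A", "Id_A", # inhibitor-bound RelA:p50
  "IkBa_C", "IkBe_C", "Id_C", # inhibitor-bound cRel:p50
  "RelB_p100",            # RelB sequestered by p100 (inactive)
  "B_nuc",                # active nuclear RelB:p52
  "NIK"
)

#' Names of the model species
#'
#' Returns the 16 species tracked by the NF-kB crosstalk model, in the order
#' used by [nfkb_derivatives()] and in exported trajectories.
#'
#' @return Character vector of species names.
#' @export
species_names <- function() .species

# Canonical parameter set. Units: minutes and arbitrary concentration units.
# Calibrated (grid + manual search, see scripts/calibrate.R) so that the
# qualitative steady-state and CD40-response constraints of the crosstalk
# mechanism hold; the constraint surface, not any individual rate, is the
# scientific content.
.default_params <- list(
  # dimer synthesis (a.u./min) and degradation (/min)
  k_syn_A  = 0.5,  k_syn_C = 0.25, k_syn_RelB = 0.5,
  k_deg_A  = 0.02, k_deg_C = 0.02, k_deg_B = 0.1,
  # NF-kB-inducible inhibitor synthesis: basal + RelA-driven Hill gain
  k0_Ia = 0.2,   g_Ia = 30, k0_Ie = 2, g_Ie = 1,
  k0_Id = 5e-4,  g_Id = 1,  h = 6, K_tx = 5,
  # association (per a.u. per min): IkBa prefers RelA, IkBd prefers cRel
  kb_Ia_A = 1,    kb_Ia_C = 0.05,
  kb_Ie_A = 2,    kb_Ie_C = 6,
  kb_Id_A = 5e-4, kb_Id_C = 1,
  # dissociation (/min)
  ku_Ia_A = 0.005, ku_Ia_C = 0.005,
  ku_Ie_A = 0.005, ku_Ie_C = 0.005,
  ku_Id_A = 0.005, ku_Id_C = 0.005,
  # inhibitor turnover: basal (/min) and IKK-driven gain (/min per IKK unit)
  d0_Ia = 0.01, d0_Ie = 0.01, d0_Id = 0.03,
  d_ikk_Ia = 200, d_ikk_Ie = 300,
  # NIK and non-canonical processing
  k_proc = 0.02, k_syn_NIK = 0.1, k_deg_NIK = 0.1,
  # nuclear transport (/min)
  k_in_A = 0.05, k_out_A = 0.02,
  k_in_C = 0.05, k_out_C = 0.02,
  # basal canonical (IKK-driving) activation fraction, 0 to 0.005
  b = 0.0005
)

# map namespaced config keys (kb.IkBd.C) onto internal names (kb_Id_C)
.key_aliases <- local({
  inh <- c(IkBa = "Ia", IkBe = "Ie", IkBd = "Id")
  al <- list()
  for (pre in c("kb", "ku")) {
    for (i in names(inh)) {
      for (d in c("A", "C")) {
        al[[paste(pre, i, d, sep = ".")]] <- paste(pre, inh[[i]], d, sep = "_")
      }
    }
  }
  al
})

#' Build a model parameter set from a scenario configuration
#'
#' Merges user-supplied values into the shipped canonical parameter set.
#' Keys may use internal names (`kb_Id_C`) or namespaced dotted names
#' (`kb.IkBd.C`). All rates must be non-negative and the affinity-ordering
#' constraints of the crosstalk mechanism must hold: IkB-delta binds cRel:p50
#' more tightly than RelA:p50 (`kb_Id_C > kb_Id_A`) while IkB-alpha prefers
#' RelA:p50 (`kb_Ia_A > kb_Ia_C`).
#'
#' @param config Named list (possibly empty) of parameter overrides, or a path
#'   to a YAML/JSON file containing one.
#' @return A named list of class `nfkb_params`.
#' @examples
#' p <- build_parameters()
#' p$b
#' p2 <- build_parameters(list(b = 0.005))
#' @export
build_parameters <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_scenario_config(config)
  }
  stopifnot(is.list(config))
  p <- .default_params
  if (length(config)) {
    if (is.null(names(config)) || any(names(config) == "")) {
      stop("config entries must be named", call. = FALSE)
    }
    for (key in names(config)) {
      internal <- if (key %in% names(.key_aliases)) .key_aliases[[key]] else key
      if (!internal %in% names(p)) {
        stop("unknown parameter key: '", key, "'", call. = FALSE)
      }
      val <- config[[key]]
      if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
        stop("parameter '", key, "' must be a single finite number",
             call. = FALSE)
      }
      p[[internal]] <- as.numeric(val)
    }
  }
  validate_parameters(p)
}

#' Validate a model parameter set
#'
#' Checks non-negativity of every rate, the inhibitor-affinity ordering
#' constraints, and the basal-activation range `b <= 0.005`.
#'
#' @param params Named list of parameters.
#' @param strict_b If `FALSE`, a basal fraction above 0.005 raises a warning
#'   instead of an error (used for sensitivity analysis).
#' @return The validated parameter list, classed `nfkb_params`.
#' @export
validate_parameters <- function(params, strict_b = TRUE) {
  missing <- setdiff(names(.default_params), names(params))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(params[names(.default_params)])
  if (any(!is.finite(vals))) stop("non-finite parameter value", call. = FALSE)
  neg <- names(vals)[vals < 0]
  if (length(neg)) {
    stop("negative rate(s): ", paste(neg, collapse = ", "), call. = FALSE)
  }
  if (params$kb_Id_C <= params$kb_Id_A) {
    stop("affinity ordering violated: kb_Id_C must exceed kb_Id_A ",
         "(IkB-delta binds cRel more tightly than RelA)", call. = FALSE)
  }
  if (params$kb_Ia_A <= params$kb_Ia_C) {
    stop("affinity ordering violated: kb_Ia_A must exceed kb_Ia_C ",
         "(IkB-alpha predominantly inhibits RelA dimers)", call. = FALSE)
  }
  if (params$b > 0.005) {
    if (strict_b) {
      stop("basal activation fraction b = ", params$b,
           " exceeds the modeled range [0, 0.005]", call. = FALSE)
    }
    warning("basal activation fraction b = ", params$b,
            " exceeds the modeled range [0, 0.005]; proceeding", call. = FALSE)
  }
  structure(params[names(.default_params)], class = "nfkb_params")
}

#' Read a scenario configuration file
#'
#' @param path YAML or JSON file with named parameter entries.
#' @return Named list.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) stop("empty config file: ", path, call. = FALSE)
  as.list(cfg)
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("<nfkb_params> canonical NF-kB crosstalk parameter set\n")
  cat("  basal activation fraction b =", x$b, "\n")
  cat("  ", length(x), "rate constants; see names(x)\n")
  invisible(x)
}
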