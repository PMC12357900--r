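# ODE right-hand side and integration for the NF-kB crosstalk model.
#
# Wiring: basal BCR/BTK signaling sets a small constitutive IKK activity
# (fraction b of maximal) that degrades IkB-alpha/-epsilon, freeing RelA:p50
# and, with it, driving synthesis of all three inhibitors including p100
# (whose multimeric form carries the IkB-delta activity that preferentially
# sequesters cRel:p50). CD40 ligation stabilizes NIK, and NIK-dependent
# processing removes p100/IkB-delta - releasing cRel:p50 from IkB-delta
# complexes and converting RelB:p100 into active nuclear RelB:p52. That makes
# the cRel arm of the CD40 response conditional on basal canonical activity.

#' Initial all-zero species state
#'
#' @return Named numeric vector over [species_names()], all zero.
#' @export
zero_state <- function() {
  stats::setNames(numeric(length(.species)), .species)
}

#' Time derivatives of the NF-kB crosstalk model
#'
#' Mass-action rates for all 16 species. Pure function: neither arguments nor
#' global state are modified.
#'
#' @param state Named numeric vector over [species_names()] (all >= 0).
#' @param params An `nfkb_params` object.
#' @param stimulus A `stimulus_spec`.
#' @param t Time in minutes (>= 0).
#' @return Named numeric vector of d(state)/dt.
#' @export
nfkb_derivatives <- function(state, params, stimulus = stimulus_spec(),
                             t = 0) {
  y <- unname(state[.species])
  p <- params

  A_cyt <- y[1];  A_nuc <- y[2];  C_cyt <- y[3];  C_nuc <- y[4]
  IkBa  <- y[5];  IkBe  <- y[6];  P100  <- y[7]
  IkBa_A <- y[8]; IkBe_A <- y[9]; Id_A <- y[10]
  IkBa_C <- y[11]; IkBe_C <- y[12]; Id_C <- y[13]
  RelB_p100 <- y[14]; B_nuc <- y[15]; NIK <- y[16]

  pulse <- 0
  if (!is.null(stimulus$bcr_pulse)) {
    pulse <- if (is.function(stimulus$bcr_pulse)) stimulus$bcr_pulse(t)
             else stimulus$bcr_pulse
  }
  ikk <- p$b * stimulus$btk_inhibitor_factor * (1 + pulse)

  deg_Ia <- p$d0_Ia + p$d_ikk_Ia * ikk    # IkB-alpha turnover, free and bound
  deg_Ie <- p$d0_Ie + p$d_ikk_Ie * ikk
  proc   <- p$k_proc * stimulus$nik_inhibitor_factor * NIK

  hillA <- A_nuc^p$h / (p$K_tx^p$h + A_nuc^p$h)

  dA_cyt <- p$k_syn_A -
    p$kb_Ia_A * A_cyt * IkBa + (p$ku_Ia_A + deg_Ia) * IkBa_A -
    p$kb_Ie_A * A_cyt * IkBe + (p$ku_Ie_A + deg_Ie) * IkBe_A -
    p$kb_Id_A * A_cyt * P100 + (p$ku_Id_A + p$d0_Id + proc) * Id_A -
    p$k_in_A * A_cyt + p$k_out_A * A_nuc - p$k_deg_A * A_cyt
  dA_nuc <- p$k_in_A * A_cyt - p$k_out_A * A_nuc - p$k_deg_A * A_nuc

  dC_cyt <- p$k_syn_C -
    p$kb_Ia_C * C_cyt * IkBa + (p$ku_Ia_C + deg_Ia) * IkBa_C -
    p$kb_Ie_C * C_cyt * IkBe + (p$ku_Ie_C + deg_Ie) * IkBe_C -
    p$kb_Id_C * C_cyt * P100 + (p$ku_Id_C + p$d0_Id + proc) * Id_C -
    p$k_in_C * C_cyt + p$k_out_C * C_nuc - p$k_deg_C * C_cyt
  dC_nuc <- p$k_in_C * C_cyt - p$k_out_C * C_nuc - p$k_deg_C * C_nuc

  dIkBa <- p$k0_Ia + p$g_Ia * hillA - deg_Ia * IkBa -
    p$kb_Ia_A * A_cyt * IkBa - p$kb_Ia_C * C_cyt * IkBa +
    p$ku_Ia_A * IkBa_A + p$ku_Ia_C * IkBa_C
  dIkBe <- p$k0_Ie + p$g_Ie * hillA - deg_Ie * IkBe -
    p$kb_Ie_A * A_cyt * IkBe - p$kb_Ie_C * C_cyt * IkBe +
    p$ku_Ie_A * IkBe_A + p$ku_Ie_C * IkBe_C
  dP100 <- p$k0_Id + p$g_Id * hillA - (p$d0_Id + proc) * P100 -
    p$kb_Id_A * A_cyt * P100 - p$kb_Id_C * C_cyt * P100 +
    p$ku_Id_A * Id_A + p$ku_Id_C * Id_C

  dIkBa_A <- p$kb_Ia_A * A_cyt * IkBa -
    (p$ku_Ia_A + deg_Ia + p$k_deg_A) * IkBa_A
  dIkBe_A <- p$kb_Ie_A * A_cyt * IkBe -
    (p$ku_Ie_A + deg_Ie + p$k_deg_A) * IkBe_A
  dId_A <- p$kb_Id_A * A_cyt * P100 -
    (p$ku_Id_A + p$d0_Id + proc + p$k_deg_A) * Id_A

  dIkBa_C <- p$kb_Ia_C * C_cyt * IkBa -
    (p$ku_Ia_C + deg_Ia + p$k_deg_C) * IkBa_C
  dIkBe_C <- p$kb_Ie_C * C_cyt * IkBe -
    (p$ku_Ie_C + deg_Ie + p$k_deg_C) * IkBe_C
  dId_C <- p$kb_Id_C * C_cyt * P100 -
    (p$ku_Id_C + p$d0_Id + proc + p$k_deg_C) * Id_C

  dRelB_p100 <- p$k_syn_RelB - (proc + p$k_deg_B) * RelB_p100
  dB_nuc <- proc * RelB_p100 - p$k_deg_B * B_nuc

  dNIK <- p$k_syn_NIK -
    p$k_deg_NIK * .nik_deg_multiplier(t, stimulus) * NIK

  stats::setNames(
    c(dA_cyt, dA_nuc, dC_cyt, dC_nuc, dIkBa, dIkBe, dP100,
      dIkBa_A, dIkBe_A, dId_A, dIkBa_C, dIkBe_C, dId_C,
      dRelB_p100, dB_nuc, dNIK),
    .species
  )
}

#' Zero all synthesis and degradation rates ("closed" test mode)
#'
#' In closed mode binding, unbinding, transport and NIK processing remain
#' active but no material enters or leaves, so each Rel-monomer total is
#' conserved exactly. Used to test mass conservation.
#'
#' @param params An `nfkb_params` object.
#' @return A new `nfkb_params` object with synthesis/degradation zeroed.
#' @export
close_system <- function(params) {
  zeroed <- c("k_syn_A", "k_syn_C", "k_syn_RelB", "k_syn_NIK",
              "k_deg_A", "k_deg_C", "k_deg_B", "k_deg_NIK",
              "k0_Ia", "k0_Ie", "k0_Id", "g_Ia", "g_Ie", "g_Id",
              "d0_Ia", "d0_Ie", "d0_Id", "d_ikk_Ia", "d_ikk_Ie")
  for (k in zeroed) params[[k]] <- 0
  validate_parameters(params, strict_b = FALSE)
}

#' Simulate the NF-kB crosstalk model
#'
#' Adaptive stiff integration (lsoda, relative and absolute tolerance 1e-8)
#' of the crosstalk model, sampled on an even output grid. Species are
#' clamped at zero on output (solver undershoot below -1e-9 is an error).
#'
#' @param params An `nfkb_params` object.
#' @param initial Named initial state (defaults to the all-zero state).
#' @param duration Duration in minutes (> 0); 1440 (24 h) is the standard
#'   CD40 co-culture horizon.
#' @param stimulus A `stimulus_spec`.
#' @param n_points Number of output time points (>= 97).
#' @param label Scenario label stored with the trajectory.
#' @return A tibble of class `nfkb_trajectory` with columns `time`, one
#'   column per species, and `scenario`.
#' @examples
#' sc <- scenario_preset("RIVA_CD40")
#' traj <- simulate_nfkb(sc$params, nfkb_steady_state(sc$params),
#'                       duration = 60, stimulus = sc$stimulus)
#' @export
simulate_nfkb <- function(params, initial = zero_state(), duration = 1440,
                          stimulus = stimulus_spec(), n_points = 97,
                          label = "scenario") {
  stopifnot(duration > 0, n_points >= 2)
  y0 <- unname(initial[.species])
  if (any(is.na(y0))) stop("initial state is missing species", call. = FALSE)
  times <- seq(0, duration, length.out = n_points)
  rhs <- function(t, y, parms) {
    names(y) <- .species
    list(unname(nfkb_derivatives(y, params, stimulus, t)))
  }
  out <- deSolve::ode(y = stats::setNames(y0, .species), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8)
  attr_d <- attributes(out)$istate
  if (nrow(out) < length(times)) {
    stop("integration failed at t = ", out[nrow(out), "time"],
         " min (of ", duration, ")", call. = FALSE)
  }
  mat <- out[, .species, drop = FALSE]
  if (any(mat < -1e-9)) {
    stop("negative concentration beyond solver tolerance (min = ",
         min(mat), ")", call. = FALSE)
  }
  mat[mat < 0] <- 0
  traj <- tibble::as_tibble(as.data.frame(mat))
  traj <- tibble::add_column(traj, time = out[, "time"], .before = 1)
  traj$scenario <- label
  class(traj) <- c("nfkb_trajectory", class(traj))
  traj
}

#' Final state of a trajectory
#'
#' @param trajectory An `nfkb_trajectory`.
#' @param t Optional time point (defaults to the last).
#' @return Named numeric state vector.
#' @export
trajectory_state <- function(trajectory, t = NULL) {
  row <- if (is.null(t)) nrow(trajectory) else which.min(abs(trajectory$time - t))
  out <- as.numeric(trajectory[row, .species])
  stats::setNames(out, .species)
}

#' Tidy (long-format) view of a trajectory
#'
#' @param trajectory An `nfkb_trajectory`.
#' @return Tibble with columns `time`, `species`, `value`, `scenario`.
#' @export
tidy_trajectory <- function(trajectory) {
  tidyr::pivot_longer(tibble::as_tibble(trajectory),
                      cols = dplyr::all_of(.species),
                      names_to = "species", values_to = "value")
}

#' Steady state of the unstimulated model
#'
#' Long-time integration (default 20,000 min, extended up to `max_rounds`
#' times if needed) without stimulus, with a convergence check on the
#' derivative norm: max |dy/dt| must fall below `tol` times the largest
#' concentration.
#'
#' @param params An `nfkb_params` object.
#' @param initial Starting state (default all-zero).
#' @param horizon Integration horizon per round (min).
#' @param tol Relative derivative tolerance (default 1e-10).
#' @param max_rounds Maximum number of horizon extensions.
#' @return Named steady-state vector with attribute `residual`.
#' @export
nfkb_steady_state <- function(params, initial = zero_state(),
                              horizon = 20000, tol = 1e-10, max_rounds = 5) {
  stim <- stimulus_spec()
  state <- initial
  for (round in seq_len(max_rounds)) {
    traj <- simulate_nfkb(params, state, duration = horizon, stimulus = stim,
                          n_points = 101, label = "relaxation")
    state <- trajectory_state(traj)
    d <- nfkb_derivatives(state, params, stim, t = 0)
    scale <- max(state, 1e-12)
    if (max(abs(d)) < tol * scale) {
      attr(state, "residual") <- max(abs(d))
      return(state)
    }
  }
  stop("steady state did not converge: residual norm ", max(abs(d)),
       " after ", max_rounds * horizon, " min", call. = FALSE)
}

#' Inhibitor composition of a dimer's bound pool
#'
#' Splits the inhibitor-bound pool of RelA:p50 (`"A"`) or cRel:p50 (`"C"`)
#' among IkB-alpha, IkB-epsilon and IkB-delta. With an empty bound pool the
#' fractions are reported as zeros with `defined = FALSE`.
#'
#' @param state Named species state vector.
#' @param dimer `"A"` (RelA:p50) or `"C"` (cRel:p50).
#' @return One-row tibble: `dimer`, `f_IkBa`, `f_IkBe`, `f_IkBd`,
#'   `bound_total`, `free_cyt`, `nuclear`, `defined`.
#' @export
inhibitor_composition <- function(state, dimer) {
  if (!dimer %in% c("A", "C")) {
    stop("dimer must be 'A' (RelA:p50) or 'C' (cRel:p50)", call. = FALSE)
  }
  sfx <- paste0("_", dimer)
  bound <- c(state[[paste0("IkBa", sfx)]], state[[paste0("IkBe", sfx)]],
             state[[paste0("Id", sfx)]])
  total <- sum(bound)
  defined <- total > 0
  fr <- if (defined) bound / total else c(0, 0, 0)
  tibble::tibble(
    dimer = dimer,
    f_IkBa = fr[1], f_IkBe = fr[2], f_IkBd = fr[3],
    bound_total = total,
    free_cyt = state[[paste0(dimer, "_cyt")]],
    nuclear = state[[paste0(dimer, "_nuc")]],
    defined = defined
  )
}
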