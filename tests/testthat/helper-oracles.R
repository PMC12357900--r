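# Independent oracles used across tests.

.with_seed_test <- function(seed, code) withr::with_seed(seed, code)

# Fixed-step classical Runge-Kutta integration of the crosstalk model.
# Shares only the derivative definition with the package's adaptive solver;
# the integration scheme itself is independent.
rk4_simulate <- function(params, initial, duration, stimulus = stimulus_spec(),
                         dt = 0.01, keep_every = NULL) {
  n_steps <- ceiling(duration / dt)
  if (is.null(keep_every)) keep_every <- max(1, floor(n_steps / 96))
  y <- initial[species_names()]
  t <- 0
  kept_t <- 0
  kept <- list(y)
  for (i in seq_len(n_steps)) {
    k1 <- nfkb_derivatives(y, params, stimulus, t)
    k2 <- nfkb_derivatives(y + dt / 2 * k1, params, stimulus, t + dt / 2)
    k3 <- nfkb_derivatives(y + dt / 2 * k2, params, stimulus, t + dt / 2)
    k4 <- nfkb_derivatives(y + dt * k3, params, stimulus, t + dt)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    if (i %% keep_every == 0 || i == n_steps) {
      kept[[length(kept) + 1]] <- y
      kept_t <- c(kept_t, t)
    }
  }
  list(times = kept_t, states = do.call(rbind, kept))
}

# Brute-force O(n * m) interval-overlap scan for TSS windows.
brute_force_window <- function(peaks, tss, half_window = 1000) {
  hits <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != tss$chrom) next
    w <- seq(tss$position - half_window, tss$position + half_window)
    iv <- seq(peaks$start[i], peaks$end[i] - 1)
    hits[i] <- length(intersect(w, iv)) > 0
  }
  hits
}

# Deterministic fake trajectory for the BCL2 layer: nuclear dimers follow
# prescribed start/end levels with a smooth saturating ramp.
fake_trajectory <- function(A0, A1, B0, B1, C0, C1, duration = 1440,
                            n = 97) {
  tt <- seq(0, duration, length.out = n)
  ramp <- function(a, b) a + (b - a) * (1 - exp(-tt / 300))
  tr <- tibble::tibble(time = tt)
  for (sp in species_names()) tr[[sp]] <- 0
  tr$A_nuc <- ramp(A0, A1)
  tr$B_nuc <- ramp(B0, B1)
  tr$C_nuc <- ramp(C0, C1)
  tr$scenario <- "fake"
  class(tr) <- c("nfkb_trajectory", class(tibble::tibble()))
  tr
}
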