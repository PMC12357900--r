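test_that("an empty system with no synthesis is a fixed point", {
  p <- build_parameters(list(k_syn_A = 0, k_syn_C = 0, k_syn_RelB = 0,
                             k_syn_NIK = 0, k0_Ia = 0, k0_Ie = 0, k0_Id = 0))
  d <- nfkb_derivatives(zero_state(), p)
  expect_true(all(d == 0))
})

test_that("NIK processing releases cRel from IkB-delta complexes", {
  p <- build_parameters()
  s <- zero_state()
  s["Id_C"] <- 5
  s["NIK"] <- 2
  d <- nfkb_derivatives(s, p)
  expect_lt(d[["Id_C"]], 0)
  expect_gt(d[["C_cyt"]], 0)
})

test_that("closed mode conserves each Rel-monomer total exactly", {
  p <- close_system(build_parameters())
  set.seed(42)
  for (rep in 1:10) {
    s <- stats::setNames(runif(16, 0, 10), species_names())
    d <- nfkb_derivatives(s, p, stimulus_spec(cd40_on = TRUE), t = 137)
    relA <- sum(d[c("A_cyt", "A_nuc", "IkBa_A", "IkBe_A", "Id_A")])
    crel <- sum(d[c("C_cyt", "C_nuc", "IkBa_C", "IkBe_C", "Id_C")])
    relB <- sum(d[c("RelB_p100", "B_nuc")])
    expect_lt(abs(relA), 1e-12 * max(abs(d)))
    expect_lt(abs(crel), 1e-12 * max(abs(d)))
    expect_lt(abs(relB), 1e-12 * max(abs(d)))
  }
})

test_that("trajectories start at the initial state and stay non-negative", {
  p <- build_parameters()
  init <- zero_state(); init["NIK"] <- 1
  tr <- simulate_nfkb(p, init, duration = 500, n_points = 101)
  expect_equal(unname(trajectory_state(tr, 0)), unname(init[species_names()]))
  expect_equal(tr$time, seq(0, 500, length.out = 101))
  expect_true(all(as.matrix(tr[species_names()]) >= 0))
})

test_that("conservation holds along closed-mode trajectories to 1e-8", {
  p <- close_system(build_parameters())
  init <- zero_state()
  init[c("A_cyt", "C_cyt", "IkBa", "IkBe", "P100", "RelB_p100", "NIK")] <-
    c(5, 3, 4, 2, 6, 4, 1)
  init[c("Id_A", "Id_C")] <- c(1, 2)
  tr <- simulate_nfkb(p, init, duration = 1440,
                      stimulus = stimulus_spec(cd40_on = TRUE))
  totals <- function(row, cols) sum(as.numeric(row[cols]))
  a_cols <- c("A_cyt", "A_nuc", "IkBa_A", "IkBe_A", "Id_A")
  c_cols <- c("C_cyt", "C_nuc", "IkBa_C", "IkBe_C", "Id_C")
  b_cols <- c("RelB_p100", "B_nuc")
  for (cols in list(a_cols, c_cols, b_cols)) {
    tot <- rowSums(as.matrix(tr[cols]))
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
  }
})

test_that("adaptive solution matches a short fixed-step RK4 oracle", {
  sc <- scenario_preset("SUDHL8_CD40")
  init <- nfkb_steady_state(sc$params)
  oracle <- rk4_simulate(sc$params, init, duration = 200,
                         stimulus = sc$stimulus, dt = 0.02,
                         keep_every = 500)   # every 10 min
  tr <- simulate_nfkb(sc$params, init, duration = 200,
                      stimulus = sc$stimulus, n_points = 21)
  got <- as.matrix(tr[species_names()])
  want <- oracle$states
  scale <- pmax(abs(want), 1e-8 * max(abs(want)))
  expect_lt(max(abs(got - want) / scale), 1e-5)
})

test_that("steady state: trivial zero system, idempotence, and stability", {
  p0 <- build_parameters(list(k_syn_A = 0, k_syn_C = 0, k_syn_RelB = 0,
                              k_syn_NIK = 0, k0_Ia = 0, k0_Ie = 0,
                              k0_Id = 0))
  expect_true(all(nfkb_steady_state(p0) == 0))

  p <- build_parameters()
  ss <- nfkb_steady_state(p)
  ss2 <- nfkb_steady_state(p, initial = ss)
  scale <- max(ss)
  expect_lt(max(abs(ss2 - ss)) / scale, 1e-9)

  tr <- simulate_nfkb(p, ss, duration = 1440)
  drift <- abs(trajectory_state(tr) - ss[species_names()])
  expect_lt(max(drift) / scale, 1e-6)
})

test_that("higher basal activation raises steady-state nuclear RelA", {
  base <- build_parameters()
  lo <- nfkb_steady_state(apply_basal_activation(base, 0.0005))
  hi <- nfkb_steady_state(apply_basal_activation(base, 0.005))
  expect_gt(hi[["A_nuc"]], lo[["A_nuc"]])
})

test_that("inhibitor composition normalizes, flags empty pools, validates", {
  s <- zero_state()
  s["Id_C"] <- 5
  comp <- inhibitor_composition(s, "C")
  expect_equal(comp$f_IkBd, 1)
  expect_equal(comp$f_IkBa + comp$f_IkBe, 0)
  expect_true(comp$defined)

  s2 <- zero_state()
  s2[c("IkBa_A", "IkBe_A", "Id_A")] <- c(1.3, 0.2, 2.2)
  comp2 <- inhibitor_composition(s2, "A")
  expect_equal(comp2$f_IkBa + comp2$f_IkBe + comp2$f_IkBd, 1,
               tolerance = 1e-9)

  empty <- inhibitor_composition(zero_state(), "A")
  expect_false(empty$defined)
  expect_equal(empty$f_IkBa + empty$f_IkBe + empty$f_IkBd, 0)

  expect_error(inhibitor_composition(zero_state(), "B"), "dimer")
})
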