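test_that("a flat trajectory induces no BCL2-family change", {
  tr <- fake_trajectory(3, 3, 0.8, 0.8, 2, 2)
  prof <- induce_bcl2_family(tr, bcl2_weights("generic"))
  expect_equal(prof$fold, rep(1, 3), tolerance = 1e-6)
})

test_that("RelB induction drives BCLXL; cRel induction drives MCL1", {
  # RelB rises only: BCLXL responds most, BCL2 not at all
  tr_b <- fake_trajectory(3, 3, 0.8, 2.2, 2, 2)
  p_b <- induce_bcl2_family(tr_b, bcl2_weights("generic"))
  folds <- stats::setNames(p_b$fold, p_b$gene)
  expect_gt(folds[["BCLXL"]], folds[["MCL1"]])
  expect_gt(folds[["BCLXL"]], 1.3)
  expect_equal(folds[["BCL2"]], 1, tolerance = 1e-6)

  # cRel rises only: MCL1 responds most
  tr_c <- fake_trajectory(3, 3, 0.8, 0.8, 1.7, 3.3)
  p_c <- induce_bcl2_family(tr_c, bcl2_weights("generic"))
  folds_c <- stats::setNames(p_c$fold, p_c$gene)
  expect_gt(folds_c[["MCL1"]], folds_c[["BCLXL"]])
  expect_gt(folds_c[["MCL1"]], 1.3)
})

test_that("simulated CD40 responses reproduce the cell-line fold pattern", {
  run_prof <- function(line, basal) {
    p <- apply_basal_activation(build_parameters(), basal)
    ss <- nfkb_steady_state(p)
    tr <- simulate_nfkb(p, ss, 1440, stimulus_spec(cd40_on = TRUE))
    prof <- induce_bcl2_family(tr, bcl2_weights(line))
    stats::setNames(prof$fold, prof$gene)
  }
  riva <- run_prof("RIVA", 0.0005)
  sudhl8 <- run_prof("SUDHL8", 0.005)
  # low-basal line: BCLXL dominates the response
  expect_gt(riva[["BCLXL"]], riva[["MCL1"]])
  expect_gt(riva[["BCLXL"]], riva[["BCL2"]])
  # high-basal line: crosstalk adds MCL1, exceeding BCL2 and the
  # low-basal line's MCL1 response
  expect_gt(sudhl8[["MCL1"]], sudhl8[["BCL2"]])
  expect_gt(sudhl8[["MCL1"]], riva[["MCL1"]])
})

test_that("viability curves are monotone with a dose-zero ceiling", {
  prof <- tibble::tibble(gene = c("BCL2", "BCLXL", "MCL1"),
                         abundance = c(100, 40, 40))
  vc <- viability_curve(prof, drug_spec("ABT199"), c(0, default_doses()))
  expect_true(all(diff(vc$viability) <= 1e-12))
  expect_equal(vc$viability[1], max(vc$viability))
  expect_error(viability_curve(prof, drug_spec("ABT199"), numeric(0)),
               "empty")
})

test_that("raising any anti-apoptotic protein weakly raises the LC50", {
  lc50_of <- function(bcl2, bclxl, mcl1) {
    prof <- tibble::tibble(gene = c("BCL2", "BCLXL", "MCL1"),
                           abundance = c(bcl2, bclxl, mcl1))
    vc <- viability_curve(prof, drug_spec("ABT199"), default_doses())
    fit_4pl(vc$dose, vc$viability)$lc50
  }
  base <- lc50_of(120, 30, 30)
  expect_gte(lc50_of(180, 30, 30), base)   # more target
  expect_gte(lc50_of(120, 70, 30), base)   # more of a compensating protein
  expect_lte(lc50_of(120, 10, 30), base)   # less compensation
})

test_that("fit_4pl recovers exact curves and flags degenerate input", {
  d <- 10^seq(-3, 1.5, length.out = 10)
  truth <- list(bottom = 0.07, top = 0.95, slope = 1.3, lc50 = 0.21)
  v <- truth$bottom + (truth$top - truth$bottom) /
    (1 + (d / truth$lc50)^truth$slope)
  fit <- fit_4pl(d, v)
  expect_true(fit$converged)
  expect_equal(fit$bottom, truth$bottom, tolerance = 1e-6)
  expect_equal(fit$top, truth$top, tolerance = 1e-6)
  expect_equal(fit$slope, truth$slope, tolerance = 1e-6)
  expect_equal(fit$lc50, truth$lc50, tolerance = 1e-6)
  expect_false(fit$extrapolated)

  flat <- fit_4pl(d, rep(1, length(d)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$lc50))

  expect_error(fit_4pl(c(1, 2, 3), c(1, 0.5, 0)), "4 distinct")
})

test_that("fit_4pl inverts viability_curve within 2% (noise-free)", {
  prof <- tibble::tibble(gene = c("BCL2", "BCLXL", "MCL1"),
                         abundance = c(120, 30, 30))
  vc <- viability_curve(prof, drug_spec("ABT199"),
                        10^seq(-4, 2, length.out = 25))
  fit <- fit_4pl(vc$dose, vc$viability)
  # the analytic half-capacity dose: capacity crosses threshold_median
  # between ceiling and floor; compare against a dense numeric inversion
  dense <- viability_curve(prof, drug_spec("ABT199"),
                           10^seq(-4, 2, length.out = 4001))
  mid <- (max(dense$viability) + min(dense$viability)) / 2
  d_mid <- dense$dose[which.min(abs(dense$viability - mid))]
  expect_equal(fit$lc50, d_mid, tolerance = 0.02)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- 10^seq(-3, 1, length.out = 8)
  v <- 0.1 + 0.8 / (1 + (d / 0.2))
  fit <- fit_4pl(d, v)
  td <- tidy(fit)
  expect_equal(td$term, c("bottom", "top", "slope", "lc50"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$lc50, td$estimate[td$term == "lc50"])
})

test_that("MCL1-high subclone profiles are venetoclax-resistant", {
  p <- apply_basal_activation(build_parameters(), 0.0005)
  tr <- simulate_nfkb(p, nfkb_steady_state(p), 1440, stimulus_spec())
  lc50 <- purrr::map_dbl(c(R1 = "U2932_R1", R2 = "U2932_R2"), function(cl) {
    prof <- induce_bcl2_family(tr, bcl2_weights(cl))
    vc <- viability_curve(prof, drug_spec("ABT199"), default_doses(),
                          dependence = dependence_profile(cl))
    fit_4pl(vc$dose, vc$viability)$lc50
  })
  expect_gt(lc50[["R1"]], 10 * lc50[["R2"]])
})
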