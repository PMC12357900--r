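test_that("flow generation is deterministic and shape-correct", {
  spec <- flow_spec(list(list(weight = 1,
    markers = list(CD20 = c(3, 0.2)))), n = 50, seed = 5)
  a <- gen_flow_sample(spec)
  b <- gen_flow_sample(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$stained), 50)
  expect_equal(nrow(a$unstained), 50)
  expect_equal(a$truth$medians[[1]][["CD20"]], 1000)

  single <- gen_flow_sample(flow_spec(list(list(weight = 1,
    markers = list(CD20 = c(2, 0.1)))), n = 1, seed = 1))
  expect_equal(nrow(single$stained), 1)
  expect_gt(single$stained$value, 0)
})

test_that("a biclonal CD20 mixture is recovered by a median split", {
  spec <- flow_spec(list(
    list(weight = 0.6, markers = list(CD20 = c(3.5, 0.15))),
    list(weight = 0.4, markers = list(CD20 = c(2.5, 0.15)))),
    n = 10000, seed = 17)
  out <- gen_flow_sample(spec)
  x <- out$stained$value
  cut <- sqrt(10^3.5 * 10^2.5)   # geometric midpoint between the two modes
  hi <- x[x > cut]; lo <- x[x <= cut]
  expect_equal(stats::median(hi), 10^3.5, tolerance = 0.05)
  expect_equal(stats::median(lo), 10^2.5, tolerance = 0.05)
  expect_equal(length(hi) / length(x), 0.6, tolerance = 0.03)
  expect_error(flow_spec(list(
    list(weight = 0.7, markers = list(CD20 = c(3, 0.1))),
    list(weight = 0.7, markers = list(CD20 = c(2, 0.1)))), n = 10),
    "sum to 1")
})

test_that("dose-response generation matches its planted 4PL exactly at
          zero noise and clips at 1.05", {
  spec0 <- dose_response_spec(noise_sd = 0, replicates = 2, seed = 3)
  out <- gen_dose_response(spec0)
  mu <- spec0$bottom + (spec0$top - spec0$bottom) /
    (1 + (out$data$dose / spec0$lc50)^spec0$slope)
  expect_equal(out$data$viability, mu)
  expect_equal(out$truth$lc50, spec0$lc50)

  noisy <- gen_dose_response(dose_response_spec(top = 1.04, noise_sd = 0.3,
                                                seed = 4))
  expect_true(all(noisy$data$viability <= 1.05))
  expect_true(all(noisy$data$viability >= 0))
  expect_identical(gen_dose_response(spec0), out)
})

test_that("N:C ratio generation plants shifts and is deterministic", {
  pops <- tibble::tibble(sample = c("mono", "co"), median = c(1, 1),
                         log_sd = c(0.25, 0.25), shift = c(1, 1.5))
  out <- gen_nc_ratios(pops, n = 2000, seed = 6)
  med <- tapply(out$data$ratio, out$data$sample, stats::median)
  expect_equal(unname(med[["mono"]]), 1, tolerance = 0.05)
  expect_equal(unname(med[["co"]]), 1.5, tolerance = 0.05)
  expect_equal(out$truth$true_median, c(1, 1.5))
  expect_identical(gen_nc_ratios(pops, n = 2000, seed = 6), out)
})

test_that("ChIP peak generation plants window membership exactly", {
  out <- gen_chip_peaks(n_in = 7, n_out = 13, seed = 8)
  expect_equal(nrow(out$peaks), 20)
  hit <- tss_window_scores(out$peaks, out$tss)
  expect_equal(nrow(hit), 7)
  expect_true(all(hit$planted_in_window))

  none <- gen_chip_peaks(n_in = 0, n_out = 0, seed = 1)
  expect_equal(nrow(none$peaks), 0)
  expect_identical(gen_chip_peaks(n_in = 7, n_out = 13, seed = 8), out)
})

test_that("planted score outliers are recovered by ROUT on window scores", {
  out <- gen_chip_peaks(n_in = 40, n_out = 10, n_outliers = 3,
                        outlier_sd = 8, seed = 12)
  scores <- tss_window_scores(out$peaks, out$tss)
  r <- rout_outliers(scores$score, q = 0.01)
  expect_true(all(out$truth$outlier_scores %in% r$outliers))
})

test_that("write_synthetic writes CSV tables plus a JSON truth sidecar", {
  dir <- withr::local_tempdir()
  out <- gen_chip_peaks(n_in = 3, n_out = 2, seed = 2)
  paths <- write_synthetic(out, dir, prefix = "chip")
  expect_true(file.exists(file.path(dir, "chip_peaks.csv")))
  expect_true(file.exists(file.path(dir, "chip_truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "chip_truth.json"))
  expect_equal(truth$n_in_window, 3)
})
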