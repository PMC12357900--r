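test_that("normalize_mfi is a ratio of medians with guarded inputs", {
  x <- c(4800, 5000, 5200)
  expect_equal(normalize_mfi(x, x), 1)
  expect_equal(normalize_mfi(c(4000, 5000, 6000), c(200, 250, 300)), 20)
  expect_error(normalize_mfi(x, c(0, 0, 0)), "positive")
  expect_error(normalize_mfi(numeric(0), x), "empty")
  # tibble inputs with a value column work identically
  expect_equal(normalize_mfi(tibble::tibble(value = x),
                             tibble::tibble(value = x / 10)), 10)
})

test_that("mfi_fold_change recovers a planted log-normal shift at n=5000", {
  spec_ctrl <- flow_spec(list(list(weight = 1,
    markers = list(MCL1 = c(3, 0.25)))), n = 5000, seed = 41)
  spec_cond <- flow_spec(list(list(weight = 1,
    markers = list(MCL1 = c(3 + log10(2.5), 0.25)))), n = 5000, seed = 42)
  ctrl <- gen_flow_sample(spec_ctrl)$stained
  cond <- gen_flow_sample(spec_cond)$stained
  fold <- mfi_fold_change(cond, ctrl)
  expect_gte(fold, 2.4)
  expect_lte(fold, 2.6)
  expect_error(mfi_fold_change(numeric(0), ctrl), "empty")
})

test_that("self-referenced z-scores standardize each marker exactly", {
  spec <- flow_spec(list(list(weight = 1,
    markers = list(RelA = c(3, 0.3), RelB = c(2.5, 0.2)))),
    n = 2000, seed = 7)
  dat <- gen_flow_sample(spec)$stained
  fp <- zscore_fingerprint(dat, markers = c("RelA", "RelB"))
  expect_equal(mean(fp$z$zx), 0, tolerance = 1e-9)
  expect_equal(stats::sd(fp$z$zx), 1, tolerance = 1e-9)
  expect_equal(mean(fp$z$zy), 0, tolerance = 1e-9)
  expect_equal(stats::sd(fp$z$zy), 1, tolerance = 1e-9)
})

test_that("the fingerprint density integrates to 1 on its grid", {
  spec <- flow_spec(list(list(weight = 1,
    markers = list(RelA = c(3, 0.3), RelB = c(2.5, 0.2)))),
    n = 1000, seed = 8)
  dat <- gen_flow_sample(spec)$stained
  fp <- zscore_fingerprint(dat, markers = c("RelA", "RelB"), grid_n = 120)
  dx <- diff(sort(unique(fp$density$x))[1:2])
  dy <- diff(sort(unique(fp$density$y))[1:2])
  expect_equal(sum(fp$density$density) * dx * dy, 1, tolerance = 1e-6)
  expect_true(all(fp$density$density >= 0))
  expect_true(all(diff(unname(fp$contour_levels)) <= 0))
})

test_that("fingerprints are invariant to a common positive rescaling and
          shift one marker when only that marker is scaled", {
  spec <- flow_spec(list(list(weight = 1,
    markers = list(RelA = c(3, 0.3), RelB = c(2.5, 0.2)))),
    n = 500, seed = 9)
  dat <- gen_flow_sample(spec)$stained
  fp <- zscore_fingerprint(dat, markers = c("RelA", "RelB"))

  scaled <- dplyr::mutate(dat, value = value * 37.5)
  fp_s <- zscore_fingerprint(scaled, markers = c("RelA", "RelB"))
  expect_equal(fp_s$z$zx, fp$z$zx, tolerance = 1e-12)
  expect_equal(fp_s$z$zy, fp$z$zy, tolerance = 1e-12)

  # scaling one marker of the sample (reference fixed) shifts only that axis
  one <- dplyr::mutate(dat,
    value = ifelse(marker == "RelA", value * 10, value))
  fp_1 <- zscore_fingerprint(one, markers = c("RelA", "RelB"),
                             reference = dat)
  sd_ref <- stats::sd(log10(dat$value[dat$marker == "RelA"]))
  expect_equal(stats::median(fp_1$z$zx) - stats::median(fp$z$zx),
               1 / sd_ref, tolerance = 1e-9)
  expect_equal(fp_1$z$zy, fp$z$zy, tolerance = 1e-12)
})

test_that("planted RelB differences order the fingerprint medians", {
  mk <- function(name, relb_med, seed) {
    spec <- flow_spec(list(list(weight = 1,
      markers = list(RelA = c(3, 0.25), RelB = c(relb_med, 0.25)))),
      n = 2000, seed = seed)
    dplyr::mutate(gen_flow_sample(spec, sample_name = name)$stained)
  }
  pool <- dplyr::bind_rows(mk("low_relb", 2.2, 10), mk("high_relb", 3.2, 11))
  fp <- zscore_fingerprint(pool, markers = c("RelA", "RelB"))
  med <- fp$medians[fp$medians$marker == "RelB", ]
  expect_gt(med$median_z[med$sample == "high_relb"],
            med$median_z[med$sample == "low_relb"])
  expect_error(
    zscore_fingerprint(dplyr::mutate(pool, value = 1),
                       markers = c("RelA", "RelB")), "variance")
})

test_that("nc_ratio_summary recovers planted medians and rejects bad rows", {
  pops <- tibble::tibble(sample = c("mono", "co"), median = c(0.8, 1.6),
                         log_sd = c(0.3, 0.3))
  dat <- gen_nc_ratios(pops, n = 2000, seed = 13)$data
  summ <- nc_ratio_summary(dat)
  expect_equal(summ$median[summ$sample == "mono"], 0.8, tolerance = 0.05)
  expect_equal(summ$median[summ$sample == "co"], 1.6, tolerance = 0.05)
  expect_true(all(c("q25", "q50", "q75") %in% names(summ)))

  one <- tibble::tibble(sample = "s", ratio = 1)
  s1 <- nc_ratio_summary(one)
  expect_equal(s1$mean, 1)
  expect_equal(s1$sd, 0)

  mixed <- tibble::tibble(sample = "s", ratio = c(1, -2, 0, 2))
  expect_message(s2 <- nc_ratio_summary(mixed), "rejected 2")
  expect_equal(s2$n, 2L)
  expect_equal(s2$n_rejected, 2L)
  expect_error(
    suppressMessages(
      nc_ratio_summary(tibble::tibble(sample = "s", ratio = c(-1, 0)))),
    "no valid")
})

test_that("TSS-window membership honors the half-open boundary convention", {
  tss <- tibble::tibble(gene = "MCL1", chrom = "chr1", position = 5000,
                        strand = "+")
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(5000, 6000, 6001, 3999, 3900),
    end = c(5001, 6100, 6101, 4000, 4000),
    score = 1:5)
  hit <- tss_window_scores(peaks, tss, half_window = 1000)
  # [5000,5001) at the TSS: in; start 6000 = position+1000: in;
  # start 6001: out; end 4000 = first base of the window, half-open: out;
  # [3900,4000) misses [4000, ...): out
  expect_setequal(hit$score, c(1, 2))
})

test_that("tss_window_scores matches brute-force overlap on random fixtures", {
  set.seed(99)
  for (rep in 1:50) {
    pos <- sample.int(1e6, 1) + 1e4
    tss <- tibble::tibble(gene = "G", chrom = "chr1", position = pos,
                          strand = "+")
    start <- pos + sample(-3000:3000, 20, replace = TRUE)
    peaks <- tibble::tibble(chrom = "chr1", start = start,
                            end = start + sample(50:500, 20, TRUE),
                            score = seq_len(20))
    got <- tss_window_scores(peaks, tss)$score
    want <- peaks$score[brute_force_window(peaks, tss)]
    expect_setequal(got, want)
  }
})

test_that("ROUT flags gross outliers and leaves clean data alone", {
  r <- rout_outliers(c(1, 1, 1, 1, 100))
  expect_equal(r$outliers, 100)
  expect_equal(r$kept, rep(1, 4))

  same <- rout_outliers(rep(3.2, 10))
  expect_length(same$outliers, 0)
  expect_equal(same$kept, rep(3.2, 10))

  expect_error(rout_outliers(c(1, 2)), "at least 3")
  expect_error(rout_outliers(1:10, q = 0.5), "0.3")
})

test_that("ROUT recovers planted contaminants with a low false-positive rate", {
  hits <- removed_clean <- numeric(0)
  for (seed in 1:60) {
    dat <- .with_seed_test(seed, {
      x <- stats::rnorm(90)
      c(x, stats::rnorm(10, mean = 8, sd = 0.5))   # >= 6 robust SD away
    })
    r <- rout_outliers(dat, q = 0.01)
    hits <- c(hits, sum(r$is_outlier[91:100]) == 10)
    clean <- .with_seed_test(seed + 1000, stats::rnorm(1000))
    rc <- rout_outliers(clean, q = 0.01)
    removed_clean <- c(removed_clean, mean(rc$is_outlier))
  }
  expect_gte(mean(hits), 0.99)
  expect_lte(mean(removed_clean), 0.02)
})
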