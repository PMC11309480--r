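# Synthetic generation, scenarios, file round trips, pipeline closure.

test_that("noiseless synthesis equals the forward model exactly", {
  m <- healthy_bulk_model(mu_Rp = 250)
  sb <- synthesize_beat(m, fs = 1000, noise_sd = 0)
  expect_equal(sb$signal, forward_bulk(m, sb$t))
  # determinism of the noise draw
  s1 <- synthesize_beat(m, fs = 1000, noise_sd = 0.05, seed = 4)
  s2 <- synthesize_beat(m, fs = 1000, noise_sd = 0.05, seed = 4)
  expect_identical(s1$signal, s2$signal)
  expect_warning(synthesize_beat(m, fs = 200, noise_sd = 0), "250 Hz")
})

test_that("generator truth fiducials follow the 3-sigma envelopes", {
  m <- healthy_bulk_model(mu_Rp = 250)
  fid <- synthesize_beat(m, fs = 1000, noise_sd = 0)$truth$fiducials
  expect_equal(fid$qrs_onset, m$mu[["Rp"]] - 3 * m$sigma[["Rp"]])
  expect_equal(fid$j_point, m$mu[["Rn"]] + 3 * m$sigma[["Rn"]])
  expect_equal(fid$t_end, m$mu[["Tp"]] + 3 * m$sigma[["Tp"]])
  expect_gte(fid$t_onset, fid$j_point)
})

test_that("stochastic generation demands a seed and refuses overlap", {
  expect_error(generator_config(n_beats = 5, noise_sd = 0.01),
               "seed")
  cfg <- generator_config(n_beats = 3, rri_mean = 300, rri_sd = 0,
                          noise_sd = 0, seed = NULL)
  expect_error(synthesize_record(cfg), "overlapping beats")
})

test_that("records are reproducible and carry a full truth table", {
  cfg <- generator_config(n_beats = 5, rri_mean = 950, rri_sd = 20,
                          noise_sd = 0.02, drift_amp = 0.05, seed = 10)
  a <- synthesize_record(cfg)
  b <- synthesize_record(cfg)
  expect_identical(a$record$signals, b$record$signals)
  expect_equal(nrow(a$truth), 5)
  expect_true(all(c("sigmaTn", "kRp", "muRTp", "qrs_onset", "t_end")
                  %in% names(a$truth)))
  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  synthesize_record(cfg)
  set.seed(123); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the ischemia scenario drifts sigmaTn before the ST shift", {
  cfg <- generator_config(n_beats = 100, scenario = "ischemia",
                          rri_mean = 900, rri_sd = 0, noise_sd = 0,
                          seed = 1,
                          scenario_opts = list(onset_sigma = 51,
                                               sigma_from = 60,
                                               sigma_to = 104,
                                               ramp_len = 50,
                                               onset_st = 66))
  sr <- synthesize_record(cfg)
  # by construction: flags fire only in the second half
  fl <- flag_thresholds(sr$truth$sigmaTn, default_threshold_rules()$sigmaTn)
  expect_true(all(fl[1:50] == "low"))  # 60 is below the 70 threshold
  expect_false(any(fl[1:73] == "high"))
  expect_true(all(fl[75:100] == "high"))
  # model ST level (kRp - kRn + beta) only moves after onset_st
  st_model <- sr$truth$kRp - sr$truth$kRn + sr$truth$beta
  expect_equal(st_model[1:65], rep(st_model[1], 65))
  expect_lt(st_model[90], st_model[1] - 0.05)
})

test_that("the ERS scenario reproduces the printed alternans structure", {
  cfg <- generator_config(n_beats = 40, scenario = "ers", rri_sd = 0,
                          noise_sd = 0, seed = 2)
  sr <- synthesize_record(cfg)
  tab <- ers_case_series()
  expect_equal(sr$truth$sigmaTn, tab$sigmaTn)
  expect_equal(sr$truth$rri, tab$RRI)
  # beat-to-beat sigmaTn variability is larger before VF (section B)
  # than in late recovery (section D)
  expect_gt(var(sr$truth$sigmaTn[11:20]), var(sr$truth$sigmaTn[31:40]))
})

test_that("CSV record round trip is exact and malformed input is refused", {
  cfg <- generator_config(n_beats = 3, rri_mean = 900, rri_sd = 0,
                          noise_sd = 0.01, seed = 6)
  sr <- synthesize_record(cfg)
  path <- tempfile(fileext = ".csv")
  write_record(sr$record, path)
  rec <- read_record(path)
  expect_equal(rec$signals, sr$record$signals, tolerance = 1e-12)
  expect_equal(rec$fs, sr$record$fs)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_record(bad), "time")
})

test_that("WFDB round trip honors gain and detects bad headers", {
  cfg <- generator_config(n_beats = 3, rri_mean = 900, rri_sd = 0,
                          noise_sd = 0.01, seed = 6)
  sr <- synthesize_record(cfg)
  base <- file.path(tempdir(), "tcgrec")
  write_record(sr$record, paste0(base, ".hea"), gain = 400)
  rec <- read_record(paste0(base, ".hea"))
  # exact up to ADC quantization (half an ADC unit at the given gain)
  expect_lt(max(abs(rec$signals - sr$record$signals)), 0.5 / 400 + 1e-9)
  expect_equal(rec$fs, 1000)
  expect_equal(rec$lead_names, "II")
  # unknown units must error, never guess
  hea <- readLines(paste0(base, ".hea"))
  hea[2] <- sub("/mV", "/uV", hea[2])
  writeLines(hea, paste0(base, ".hea"))
  expect_error(read_record(paste0(base, ".hea")), "units")
  writeLines("garbage", paste0(base, ".hea"))
  expect_error(read_record(paste0(base, ".hea")), "header")
})

test_that("fitted parameters across noisy beats cover the truth", {
  # generator/fitter closure: 95% CI of fitted values contains the
  # generating value for each headline parameter; the generating model
  # satisfies the fitter's plateau constraint (closed trapezoids)
  p <- healthy_reference_params("bulk")
  p$kTp <- p$kRp; p$kTn <- p$kRn
  m <- reference_beat_model(p, "bulk", mu_Rp = 100)
  vals <- matrix(NA_real_, 60, 3,
                 dimnames = list(NULL, c("sigmaTn", "sigmaTp", "muRTp")))
  for (i in 1:60) {
    sb <- synthesize_beat(m, fs = 500, noise_sd = 0.02, seed = 3000 + i)
    f <- fit_rt_bulk(sb$signal, sb$fs, sb$truth$fiducials)
    vals[i, ] <- c(f$model$sigma[["Tn"]], f$model$sigma[["Tp"]],
                   f$metrics$muRTp)
  }
  truth <- c(50.07, 35.73, 299.98)
  for (j in 1:3) {
    ci <- quantile(vals[, j], c(0.025, 0.975))
    expect_gte(truth[j], ci[[1]])
    expect_lte(truth[j], ci[[2]])
  }
})

test_that("end-to-end: pipeline on a generated record recovers per-beat truth", {
  p <- healthy_reference_params("bulk")
  p$kTp <- p$kRp; p$kTn <- p$kRn
  cfg <- generator_config(n_beats = 12, rri_mean = 900, rri_sd = 10,
                          noise_sd = 0.01, seed = 9, params = p)
  sr <- synthesize_record(cfg)
  res <- fit_record(sr$record, config = fit_config("bulk"))
  expect_true(all(res$tensor$info$converged))
  mrtp <- extract_series(res$tensor, "muRTp")
  expect_true(all(abs(mrtp - sr$truth$muRTp) / sr$truth$muRTp < 0.01))
  # with generator-truth windows instead of the delineator
  res2 <- fit_record(sr$record, config = fit_config("bulk"),
                     fiducials = truth_fiducials(sr$truth))
  mrtp2 <- extract_series(res2$tensor, "muRTp")
  expect_true(all(abs(mrtp2 - sr$truth$muRTp) / sr$truth$muRTp < 0.005))
})

test_that("the command-line front end is deterministic given a seed", {
  cli <- system.file("cli", "tcg.R", package = "tensorcardio")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  d <- withr::local_tempdir()
  run <- function(out) {
    system2(rscript,
            c(cli, "simulate", "--beats", "5", "--seed", "11",
              "--out", file.path(d, out), "--format", "csv",
              "--log-level", "quiet"),
            stdout = FALSE, stderr = FALSE)
  }
  expect_equal(run("a"), 0L)
  expect_equal(run("b"), 0L)
  expect_identical(readLines(file.path(d, "a.csv")),
                   readLines(file.path(d, "b.csv")))
  # unknown command exits non-zero
  bad <- system2(rscript, c(cli, "frobnicate"), stdout = FALSE,
                 stderr = FALSE)
  expect_gt(bad, 0L)
})
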