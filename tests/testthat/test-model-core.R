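# Forward model: CDF legs, waveform assembly, derived metrics,
# repolarization-crossing detection.

test_that("eval_component matches the Gaussian CDF in both directions", {
  rising <- cdf_component("anodic", "rising", mu = 10, sigma = 5, k = 2)
  expect_equal(eval_component(rising, 10), 1.0)  # k * Phi(0)
  falling <- cdf_component("anodic", "falling", mu = 10, sigma = 5, k = 2)
  expect_equal(eval_component(falling, 1e6), 0.0)
  expect_equal(eval_component(falling, -1e6), 2.0)
  expect_equal(eval_component(rising, -1e6), 0.0)

  # against an independent erf-based normal CDF (population sigma/k)
  skip_if_not_installed("pracma")
  phi1 <- 0.5 * (1 + pracma::erf(1 / sqrt(2)))
  c1 <- cdf_component("anodic", "rising", mu = 0, sigma = 6.71, k = 1.99)
  expect_equal(eval_component(c1, 6.71), 1.99 * phi1, tolerance = 1e-12)
})

test_that("component construction rejects invalid parameters", {
  expect_error(cdf_component("anodic", "rising", 0, sigma = 0, k = 1),
               "sigma")
  expect_error(cdf_component("anodic", "rising", 0, sigma = -3, k = 1),
               "sigma")
  expect_error(cdf_component("anodic", "rising", 0, sigma = 5, k = -1),
               "'k'")
})

test_that("components are monotone in the stated direction", {
  t <- seq(-100, 100, by = 0.5)
  rising <- cdf_component("cathodic", "rising", mu = 3, sigma = 7, k = 1.5)
  expect_true(all(diff(eval_component(rising, t)) >= 0))
  falling <- cdf_component("cathodic", "falling", mu = 3, sigma = 7, k = 1.5)
  expect_true(all(diff(eval_component(falling, t)) <= 0))
})

test_that("identical anodic and cathodic legs cancel to the level", {
  m <- beat_model(mu = c(Rp = 100, Rn = 100, Tn = 300, Tp = 300),
                  sigma = c(Rp = 5, Rn = 5, Tn = 40, Tp = 40),
                  k = c(Rp = 2, Rn = 2, Tn = 1, Tp = 1),
                  beta = c(R = 0.3, T = -0.1), mode = "separate")
  t <- seq(0, 500, by = 1)
  expect_equal(forward_separate(m, t, "R"), rep(0.3, length(t)))
  expect_equal(forward_separate(m, t, "T"), rep(-0.1, length(t)))
  # far left of the R window both rising CDFs vanish
  m2 <- healthy_separate_model()
  expect_equal(forward_separate(m2, -1e5, "R"), m2$beta[["R"]])
})

test_that("R-wave peak lies between the two depolarization means", {
  m <- healthy_separate_model(mu_Rp = 100)
  t <- seq(0, 250, by = 0.1)
  y <- forward_separate(m, t, "R")
  expect_gt(max(y), 0)
  t_peak <- t[which.max(y)]
  expect_gt(t_peak, m$mu[["Rp"]])
  expect_lt(t_peak, m$mu[["Rn"]])
})

test_that("bulk trapezoids close and reproduce the model ST level", {
  m <- healthy_bulk_model()
  # far beyond the T wave with equalized weights the signal returns to
  # beta (weights differ slightly here, so equalize first)
  me <- beat_model(mu = m$mu, sigma = m$sigma,
                   k = c(Rp = 1.9, Rn = 1.8, Tn = 1.8, Tp = 1.9),
                   beta = 0.05, mode = "bulk")
  expect_equal(forward_bulk(me, 5000), 0.05, tolerance = 1e-12)
  # at the plateau the level is kRp - kRn + beta
  t_plateau <- (me$mu[["Rn"]] + 3 * me$sigma[["Rn"]] +
                  me$mu[["Tn"]] - 3 * me$sigma[["Tn"]]) / 2
  expect_equal(forward_bulk(me, t_plateau), 1.9 - 1.8 + 0.05,
               tolerance = 1e-3)
})

test_that("the healthy bulk waveform has exactly two positive lobes", {
  m <- healthy_bulk_model(mu_Rp = 150)
  t <- seq(0, 700, by = 0.5)
  y <- forward_bulk(m, t)
  above <- y > 0.2  # above the ST plateau (kRp - kRn ~ 0.09 mV)
  runs <- rle(above)
  expect_equal(sum(runs$values & runs$lengths > 10), 2L)
})

test_that("interval metrics reproduce the population table and its sum rule", {
  m <- beat_model(mu = c(Rp = 0, Rn = 22.18, Tn = 253.88, Tp = 307.36),
                  sigma = c(Rp = 6.71, Rn = 5.83, Tn = 54.29, Tp = 23.56),
                  k = c(Rp = 1.99, Rn = 2.01, Tn = 0.8, Tp = 0.8),
                  beta = c(R = 0, T = 0), mode = "separate")
  met <- derive_metrics(m)
  expect_equal(met$muRTp, 307.36)
  expect_equal(met$muRTn, 231.70)
  expect_equal(met$muRpn, 22.18)
  expect_equal(met$muTpn, 53.48)
  # reconstructing muRTp from the printed intervals lands within
  # rounding (0.02 ms) of the printed 307.35
  p <- healthy_reference_params("separate")
  expect_lt(abs((p$muRpn + p$muRTn + p$muTpn) - p$muRTp), 0.02 + 1e-9)
})

test_that("the interval identity holds exactly for random models", {
  withr::with_seed(11, {
    for (i in 1:50) {
      m <- random_beat_model()
      met <- derive_metrics(m)
      expect_equal(met$muRpn + met$muRTn + met$muTpn, met$muRTp,
                   tolerance = 1e-12)
    }
  })
  # degenerate: all means equal
  m0 <- beat_model(mu = c(Rp = 50, Rn = 50, Tn = 50, Tp = 50),
                   sigma = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
                   k = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
                   beta = 0, mode = "bulk")
  met0 <- derive_metrics(m0)
  expect_identical(c(met0$muRTp, met0$muRTn, met0$muRpn, met0$muTpn),
                   c(0, 0, 0, 0))
})

test_that("bulk equals stitched separate segments when plateaus close", {
  # equal anodic and cathodic weight pairs, windows away from plateau
  mu <- c(Rp = 100, Rn = 120, Tn = 350, Tp = 410)
  sigma <- c(Rp = 6, Rn = 5, Tn = 35, Tp = 25)
  k <- c(Rp = 1.8, Rn = 1.7, Tn = 1.7, Tp = 1.8)
  mb <- beat_model(mu, sigma, k, beta = 0.1, mode = "bulk")
  ms <- beat_model(mu, sigma, k, beta = c(R = 0.1, T = 0.1),
                   mode = "separate")
  tR <- seq(60, 140, by = 0.5)   # T legs still near zero rise
  yb <- forward_bulk(mb, tR)
  # on the R window the falling pairs have not risen yet, so the bulk
  # model reduces exactly to the R-segment difference
  ys <- forward_separate(ms, tR, "R")
  expect_lt(max(abs(yb - ys)), 1e-6)  # residual Gaussian tail mass
  tT <- seq(260, 560, by = 0.5)  # R legs saturated
  yb2 <- forward_bulk(mb, tT)
  ys2 <- forward_separate(ms, tT, "T") + (k[["Rp"]] - k[["Rn"]]) -
    (k[["Tp"]] - k[["Tn"]])
  expect_equal(yb2, ys2, tolerance = 1e-9)
})

test_that("repolarization crossing is found when cathodic tail outlasts", {
  # identical falling curves: no crossing
  m_eq <- beat_model(mu = c(Rp = 100, Rn = 120, Tn = 350, Tp = 350),
                     sigma = c(Rp = 6, Rn = 5, Tn = 30, Tp = 30),
                     k = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
                     beta = 0, mode = "bulk")
  expect_false(find_repolarization_crossing(m_eq)$crossed)
  # equal sigma, anodic later: anodic strictly above, no inversion
  m_no <- beat_model(mu = c(Rp = 100, Rn = 120, Tn = 340, Tp = 400),
                     sigma = c(Rp = 6, Rn = 5, Tn = 30, Tp = 30),
                     k = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
                     beta = 0, mode = "bulk")
  expect_false(find_repolarization_crossing(m_no)$crossed)
  # ERS-like sigmas (sigmaTn >> sigmaTp): cathodic tail crosses late
  m_yes <- beat_model(mu = c(Rp = 100, Rn = 122, Tn = 353.9, Tp = 407.4),
                      sigma = c(Rp = 6.9, Rn = 3.8, Tn = 89.01,
                                Tp = 28.29),
                      k = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
                      beta = 0, mode = "bulk")
  cr <- find_repolarization_crossing(m_yes)
  expect_true(cr$crossed)
  expect_gt(cr$time, m_yes$mu[["Tp"]])
  # dense-grid oracle: beyond the crossing the cathodic curve is higher
  t_after <- cr$time + c(1, 10, 30)
  fTp <- m_yes$k[["Tp"]] *
    (1 - pnorm((t_after - m_yes$mu[["Tp"]]) / m_yes$sigma[["Tp"]]))
  fTn <- m_yes$k[["Tn"]] *
    (1 - pnorm((t_after - m_yes$mu[["Tn"]]) / m_yes$sigma[["Tn"]]))
  expect_true(all(fTn > fTp))
})

test_that("model construction enforces the documented contracts", {
  expect_error(beat_model(mu = c(Rp = 1, Rn = 2, Tn = 3, Tp = 4),
                          sigma = c(Rp = -1, Rn = 1, Tn = 1, Tp = 1),
                          k = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1)),
               "sigma")
  expect_error(forward_separate(healthy_separate_model(), numeric(0), "R"),
               "empty")
  expect_error(forward_bulk(healthy_separate_model(), 1:10), "bulk")
  # ordering violations are flagged, never reordered
  m <- beat_model(mu = c(Rp = 200, Rn = 120, Tn = 350, Tp = 400),
                  sigma = c(Rp = 6, Rn = 5, Tn = 30, Tp = 30),
                  k = c(Rp = 1, Rn = 1, Tn = 1, Tp = 1),
                  beta = 0, mode = "bulk")
  expect_true(ordering_violated(m))
  expect_equal(m$mu[["Rp"]], 200)
})
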