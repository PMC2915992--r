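# SBL fit, amplitudes, t-statistics, backward elimination, thresholding

test_that("constant signals yield no breakpoints", {
  for (y in list(rep(0, 10), rep(1.5, 100), rep(-2, 37))) {
    f <- sbl_fit(y)
    expect_length(f$breakpoints, 0)
    expect_true(f$converged)
  }
})

test_that("a clean step is found exactly and matches the scan oracle", {
  set.seed(101)
  y <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.1)
  f <- sbl_fit(y, a = 0.5)
  expect_equal(f$breakpoints, 50L)
  expect_equal(f$breakpoints, scan_oracle(y))
  # deterministic: bit-identical re-run
  f2 <- sbl_fit(y, a = 0.5)
  expect_identical(f[c("breakpoints", "w", "alpha", "sigma2")],
                   f2[c("breakpoints", "w", "alpha", "sigma2")])
})

test_that("larger a gives a sparser (nested-size) active set", {
  set.seed(102)
  for (r in 1:5) {
    y <- c(rep(0, 60), rep(0.8, 40)) + rnorm(100, 0, 0.2)
    n02 <- length(sbl_fit(y, a = 0.2)$breakpoints)
    n08 <- length(sbl_fit(y, a = 0.8)$breakpoints)
    expect_lte(n08, n02)
  }
})

test_that("sbl_fit validates inputs", {
  expect_error(sbl_fit(c(1, NA, 2)), "finite")
  expect_error(sbl_fit(c(1, 2), a = 0), "a must")
  expect_error(sbl_fit(c(1, 2), a = 1.5), "a must")
  expect_error(sbl_fit(c(1, 2), b = -1), "b must")
  expect_error(sbl_fit(numeric(1)), "at least 2")
})

test_that("fit_amplitudes returns exact segment means", {
  expect_equal(fit_amplitudes(c(1, 1, 3, 3), 2), c(1, 3))
  expect_equal(fit_amplitudes(c(0, 0, 0, 6), 3), c(0, 6))
  y <- rnorm(30)
  expect_equal(fit_amplitudes(y, integer(0)), mean(y))
  # residuals sum to zero within every segment
  b <- c(4, 11, 20)
  amps <- fit_amplitudes(y, b)
  bounds <- c(0, b, 30)
  for (s in seq_along(amps)) {
    idx <- (bounds[s] + 1):bounds[s + 1]
    expect_equal(sum(y[idx] - amps[s]), 0, tolerance = 1e-12)
  }
  expect_error(fit_amplitudes(y, c(4, 4)), "duplicate")
  expect_error(fit_amplitudes(y, 30), "range")
})

test_that("t-statistic matches the closed-form two-sample reduction", {
  # L1 = 4 (mean 1), L2 = 2 (mean 2), sigma = 1
  y <- c(1, 1, 1, 1, 2, 2)
  expect_equal(t_statistics(y, 4, 1), 1 / sqrt(1 / 4 + 1 / 2),
               tolerance = 1e-10)
  # random two-segment signals, 1e-10 relative agreement
  set.seed(103)
  for (r in 1:20) {
    L1 <- sample(2:30, 1); L2 <- sample(2:30, 1)
    y <- c(rnorm(L1, 0), rnorm(L2, 2))
    s2 <- runif(1, 0.25, 4)
    m1 <- mean(y[1:L1]); m2 <- mean(y[(L1 + 1):(L1 + L2)])
    closed <- abs(m2 - m1) / sqrt(s2 * (1 / L1 + 1 / L2))
    expect_equal(t_statistics(y, L1, s2), closed, tolerance = 1e-10)
  }
  # zero step -> t = 0
  expect_equal(t_statistics(rep(1, 8), 4, 1), 0)
  # doubling sigma halves t
  y <- c(rep(0, 5), rep(1, 5))
  expect_equal(t_statistics(y, 5, 4), t_statistics(y, 5, 1) / 2)
  expect_error(t_statistics(y, 5, 0), "sigma2")
})

test_that("short segments are forced out before ordinary elimination", {
  set.seed(104)
  y <- c(rep(0, 20), 5, rep(0, 20), rep(3, 30)) + rnorm(71, 0, 0.1)
  sig <- make_signal(y)
  fit <- sbl_fit(sig, a = 0.2)
  # SBL isolates the 1-probe blip
  expect_true(all(c(20, 21) %in% fit$breakpoints))
  rk <- backward_eliminate(sig, fit, min_seg_len = 3)
  # at least one blip-bounding breakpoint is a forced removal, and no
  # threshold can produce a segment shorter than min_seg_len
  expect_true(any(rk$order$forced &
                    rk$order$breakpoint %in% c(20L, 21L)))
  for (T in c(0, 3, 5, 10)) {
    seg <- apply_threshold(rk, T, sig)
    expect_true(all(seg$segments$n_probes >= 3))
  }
  # the genuine step at 41 survives a T = 5 threshold
  expect_true(41L %in% survivors_at(rk, 5))
  # without the length constraint the blip is kept as its own segment
  rk1 <- backward_eliminate(sig, fit, min_seg_len = 1)
  expect_true(all(c(20L, 21L) %in% survivors_at(rk1, 5)))
})

test_that("empty fits give empty rankings; thresholds behave at extremes", {
  sig <- make_signal(rep(2, 30))
  fit <- sbl_fit(sig)
  rk <- backward_eliminate(sig, fit)
  expect_equal(nrow(rk$order), 0)
  expect_length(survivors_at(rk, 0), 0)

  set.seed(105)
  sig2 <- make_signal(c(rep(0, 30), rep(1, 30)) + rnorm(60, 0, 0.1))
  fit2 <- sbl_fit(sig2)
  rk2 <- backward_eliminate(sig2, fit2, min_seg_len = 1)
  # T = 0 keeps every SBL breakpoint; T = Inf leaves a single segment
  expect_setequal(survivors_at(rk2, 0), fit2$breakpoints)
  seg_inf <- apply_threshold(rk2, Inf, sig2)
  expect_equal(nrow(seg_inf$segments), 1)
  seg0 <- apply_threshold(rk2, 0, sig2)
  expect_equal(nrow(seg0$segments), length(fit2$breakpoints) + 1)
})

test_that("survivor sets are nested and non-increasing in T", {
  set.seed(106)
  for (r in 1:20) {
    y <- rnorm(150, 0, 0.3) +
      rep(sample(c(-1, 0, 0.6), 5, replace = TRUE),
          times = c(40, 30, 30, 30, 20))
    sig <- make_signal(y)
    rk <- backward_eliminate(sig, sbl_fit(sig, a = 0.3), min_seg_len = 3)
    prev <- NULL
    for (T in c(0, 2, 3, 4, 5, 8, 16)) {
      s <- survivors_at(rk, T)
      if (!is.null(prev)) expect_true(all(s %in% prev))
      prev <- s
    }
  }
})

test_that("apply_threshold enforces ranking consistency", {
  sig <- make_signal(c(rep(0, 10), rep(1, 10)))
  rk <- backward_eliminate(sig, sbl_fit(sig, sigma2_init = 0.01),
                           min_seg_len = 3)
  expect_error(apply_threshold(rk, 4, sig, min_seg_len = 5), "min_seg_len")
  expect_silent(apply_threshold(rk, 4, sig, min_seg_len = 3))
})
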