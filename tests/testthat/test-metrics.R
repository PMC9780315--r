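test_that("decay time of a pure exponential is tau*ln(10)", {
  dt <- 1e-3
  tr <- exp(-seq(0, 2, by = dt) / 0.1)
  expect_equal(decay_time_to_10pct(tr, dt), 0.1 * log(10), tolerance = 1e-3)
  # sign does not matter
  expect_equal(decay_time_to_10pct(-tr, dt), 0.1 * log(10), tolerance = 1e-3)
})

test_that("two-exponential decay matches a dense-grid search oracle", {
  mix <- function(t) 0.7 * exp(-t / 0.05) - 0.5 * exp(-t / 0.4)
  dt <- 5e-3
  t <- seq(0, 3, by = dt)
  got <- decay_time_to_10pct(mix(t), dt)
  tf <- seq(0, 3, by = dt / 10)
  v <- abs(mix(tf))
  pk <- which.max(v)
  cross <- pk - 1 + which(v[pk:length(v)] < 0.1 * v[pk])[1]
  oracle <- (cross - pk) * dt / 10
  expect_lt(abs(got - oracle), dt / 2)
})

test_that("undefined decays are flagged", {
  expect_true(is.na(decay_time_to_10pct(rep(0, 100), 1e-3)))
  # never drops below 10% of its peak
  expect_true(is.na(decay_time_to_10pct(seq(1, 0.5, length.out = 100), 1e-3)))
})

test_that("pause metrics recover closed-form Gaussian-dip geometry", {
  fx <- make_fixture("synthetic-pause")
  pm <- pause_metrics(fx$pc, fx$time, t_target = 0.2)
  expect_equal(pm$h_spont, 40, tolerance = 1e-6)
  expect_equal(pm$amplitude, 20, tolerance = 1e-3)
  expect_equal(pm$fwhm, 2 * fx$sigma * sqrt(2 * log(2)), tolerance = 1e-3)
  expect_equal(pm$epsilon_t, 0.05, tolerance = 0.0026)  # bin-center offset
  expect_equal(pm$epsilon_tot,
               (1 - 0.5) + pm$fwhm + 5 * pm$epsilon_t, tolerance = 1e-12)
})

test_that("flat traces get the documented degenerate conventions", {
  time <- seq(-0.1, 1.4, by = 5e-3)
  pm <- pause_metrics(rep(40, length(time)), time, 0.2)
  expect_equal(pm$amplitude, 0)
  expect_false(pm$fwhm_defined)
  expect_equal(pm$epsilon_tot, 1 + pm$fwhm)  # window-length penalty
})

test_that("amplitude, width and timing are shift-invariant", {
  fx <- make_fixture("synthetic-pause")
  a <- pause_metrics(fx$pc, fx$time, 0.2)
  b <- pause_metrics(fx$pc + 7, fx$time, 0.2)
  expect_equal(a$amplitude, b$amplitude)
  expect_equal(a$fwhm, b$fwhm)
  expect_equal(a$epsilon_t, b$epsilon_t)
})

test_that("BLS estimator limits and monotonicity", {
  pr <- c(0.1, 0.3)
  # near-noiseless measurement inside the support
  expect_equal(bls_estimate(0.2, pr, 1e-3), 0.2, tolerance = 1e-4)
  # measurement far outside concentrates the posterior at the boundary
  # (scalar noise spreads the low side slightly, so "near", not "at")
  expect_lt(bls_estimate(0.01, pr, 0.05), pr[1] + 0.015 * diff(pr))
  expect_equal(bls_estimate(2, pr, 0.05), pr[2], tolerance = 1e-3)
  # monotone non-decreasing over the measured range (the prior support)
  tm <- seq(pr[1], pr[2], by = 0.005)
  te <- bls_estimate(tm, pr, 0.12)
  expect_true(all(diff(te) >= -1e-12))
  expect_true(all(te >= pr[1] & te <= pr[2]))
  # degenerate prior
  expect_equal(bls_estimate(0.5, c(0.2, 0.2), 0.1), 0.2)
})

test_that("BLS quadrature agrees with a Monte-Carlo posterior mean", {
  pr <- c(0.1, 0.3); w <- 0.12; tm <- 0.12
  set.seed(123)
  ts <- runif(1e6, pr[1], pr[2])
  lik <- dnorm(tm, ts, w * ts)
  mc <- sum(ts * lik) / sum(lik)
  se <- sd(ts * lik / mean(lik) - mc * lik / mean(lik)) / sqrt(1e6)
  expect_lt(abs(bls_estimate(tm, pr, w) - mc), 3 * se + 1e-5)
})

test_that("Weber-fraction fit recovers a planted value", {
  fx <- make_fixture("bls-curves")
  fit <- fit_weber(fx$curves, fx$priors)
  expect_lt(abs(fit$w_weber - fx$w_planted), 0.005)
  expect_false(fit$boundary)
  expect_length(fit$sse_per_prior, 5)
  # symmetric noise leaves the minimizer essentially unbiased
  set.seed(2)
  noisy <- lapply(fx$curves, function(cu) {
    cu$t_e <- cu$t_e + rnorm(nrow(cu), 0, 0.003); cu
  })
  fit_n <- fit_weber(noisy, fx$priors)
  expect_lt(abs(fit_n$w_weber - fx$w_planted), 0.015)
})

test_that("a zero-bias (identity) curve drives the fit to the boundary", {
  pr <- list(c(0.1, 0.3))
  tm <- seq(0.1, 0.3, length.out = 50)
  expect_warning(fit <- fit_weber(list(data.frame(t_m = tm, t_e = tm)), pr),
                 "boundary")
  expect_lt(fit$w_weber, 0.0102)
})

test_that("transient-amplitude / time-constant sampling behaves", {
  reg <- builtin_registry("table3")
  spec <- builtin_rate_spec("reduced-reference")
  jd <- joint_At_tau_density(spec, reg, n = 5000, seed = 12, grid_n = 31)
  s <- jd$samples
  expect_true(all(s$m > 0))  # zero post-switch rates excluded
  for (g in 1:2) {
    for (pool in c("slow", "fast")) {
      tau_ref <- if (pool == "slow") reg$tau_ref_slow[g] else
        reg$tau_ref_fast[g]
      sub <- s[s$group_id == reg$group_id[g] & s$pool == pool, ]
      expect_true(all(sub$tau_syn <= tau_ref + 1e-12))
    }
  }
  # sample mean of A_t vs a dense quadrature oracle (driver slow pool)
  sub <- s[s$group_id == "driver" & s$pool == "slow", ]
  p <- rectified_gaussian_params(200, 15)
  qs <- seq(-6, 6, length.out = 2001)
  mgrid <- pmax(p[["mu0"]] + p[["sigma0"]] * qs, 0)
  wts <- dnorm(qs); wts <- wts / sum(wts)
  keep <- mgrid > 0
  # E[A_t] = E_mpre E_m>0 [A_t(m_pre, m)] restricted to m > 0
  A <- outer(mgrid[keep], mgrid, function(m, mpre)
    transient_decomposition(3.5, 0.8, mpre, m, 2, 0.6, "slow")$A_t)
  w2 <- outer(wts[keep] / sum(wts[keep]), wts)
  oracle <- sum(A * w2)
  se <- sd(sub$A_t) / sqrt(nrow(sub))
  expect_lt(abs(mean(sub$A_t) - oracle), 4 * se)
})

test_that("degenerate rate ensembles give zero transients", {
  reg <- builtin_registry("table3")
  spec <- mf_rate_spec(c("driver", "supporter"), "tgauss",
                       mean = c(100, 20), sd = 0, occurrence = c(0.5, 0.5))
  jd <- joint_At_tau_density(spec, reg, n = 200, seed = 3, grid_n = 11)
  expect_true(all(abs(jd$samples$A_t) < 1e-12))
})
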