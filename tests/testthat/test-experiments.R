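test_that("identical patterns produce no transients; repeats are bit-equal", {
  m <- tiny_full_model()
  ps1 <- run_pattern_switch(m, n_switches = 3, c = 1, seed = 81)
  expect_lt(max(ps1$amplitudes), 1e-8)
  ps_a <- run_pattern_switch(m, n_switches = 3, c = 0, seed = 82)
  ps_b <- run_pattern_switch(m, n_switches = 3, c = 0, seed = 82)
  expect_identical(ps_a$amplitudes, ps_b$amplitudes)
  expect_identical(ps_a$trace$pc, ps_b$trace$pc)
})

test_that("transient variability falls as pattern correlation rises", {
  m <- small_full_model()
  sc <- pattern_switch_scan(m, c_values = c(0, 0.85, 1), n_switches = 16,
                            seed = 83)
  expect_equal(sc$normalized_sd[1], 1)
  expect_lt(sc$normalized_sd[2], 1)
  expect_lt(sc$normalized_sd[3], 0.05)
})

test_that("frozen synapses leave only membrane-time-scale transients", {
  # with frozen synapses the only dynamics left is the 10 ms GC membrane
  # filter: deviations from the settled value vanish within ~10 tau_g,
  # whereas live STP keeps relaxing over hundreds of milliseconds
  m <- small_full_model()
  on <- run_pattern_switch(m, n_switches = 3, c = 0, seed = 84)
  off <- run_pattern_switch(m, n_switches = 3, c = 0, seed = 84,
                            stp_off = TRUE)
  late_dev <- function(ps, t_after) {
    tr <- ps$trace
    steps <- round(1 / tr$dt)
    vapply(1:3, function(s) {
      idx <- (s * steps + 1):((s + 1) * steps)
      tail_ref <- mean(tr$pc[idx[idx > max(idx) - steps %/% 20]])
      late <- idx[idx > s * steps + round(t_after / tr$dt)]
      max(abs(tr$pc[late] - tail_ref))
    }, numeric(1))
  }
  # 100 ms after each switch the frozen-synapse PC has settled ...
  expect_lt(max(late_dev(off, 0.1) / off$amplitudes), 0.02)
  # ... while the live-synapse PC is still far from its settled value
  expect_gt(max(late_dev(on, 0.1) / on$amplitudes), 0.2)
})

test_that("eyelid conditioning learns a pause; controls do not", {
  m <- small_full_model()
  cfg <- learning_config(n_trials = 600)
  res <- run_eyelid(m, delays = c(0.025, 0.25), cfg, seed = 85)
  amp <- vapply(res$metrics, `[[`, numeric(1), "amplitude")
  base <- vapply(res$metrics, `[[`, numeric(1), "h_spont")
  expect_true(all(amp > 0.1 * base))
  # minimum of the shortest delay lands within one bin of the target
  expect_lte(abs(res$metrics[[1]]$t_min - 0.025), 0.005 + 1e-9)
  off <- run_eyelid(m, delays = 0.25, cfg, stp_off = TRUE, seed = 85)
  expect_lt(off$metrics[[1]]$amplitude, 0.1 * off$metrics[[1]]$h_spont)
})

test_that("ablating slow GCs hurts long delays more than short ones", {
  m <- small_full_model()
  cfg <- learning_config(n_trials = 600)
  pats <- sample_mf_pattern(m$rate_spec, m$mf_groups, 2, seed = 23)
  basis <- gc_basis(m, pats[, 1], pats[, 2], cfg)
  cls <- classify_gc_speed(basis, cfg$dt * cfg$subsample_factor,
                           threshold = 0.15)
  expect_gt(length(cls$slow), 0)
  delays <- c(0.025, 0.3)
  full <- run_eyelid(m, delays, cfg, seed = 23)
  mask <- run_eyelid(m, delays, cfg, gc_mask = cls$slow, seed = 23)
  d_err <- vapply(mask$metrics, `[[`, numeric(1), "epsilon_tot") -
    vapply(full$metrics, `[[`, numeric(1), "epsilon_tot")
  expect_gt(d_err[2], d_err[1])
})

test_that("interval-estimation pipeline: rescale is exact and affine", {
  m <- small_full_model()
  cfg <- learning_config(n_trials = 600)
  priors <- list(c(0.1, 0.3), c(0.2, 0.4))
  b <- suppressWarnings(run_bayes(m, priors, cfg, i_ext_mode = "trace",
                                  seed = 86))
  for (p in 1:2) {
    rc <- b$rescaled[[p]]
    expect_equal(range(rc$t_e), priors[[p]], tolerance = 1e-12)
    # affine: rescaled curve correlates perfectly with the dn curve
    expect_equal(abs(cor(rc$t_e, b$dn_curves[[p]]$dn)), 1, tolerance = 1e-10)
  }
  expect_true(is.finite(b$fit$w_weber))
  # long priors get the raised CF baseline without touching the input config
  expect_equal(cfg$cf_spont, 1)
})

test_that("without learning the DN output is identically zero", {
  m <- tiny_full_model()
  cfg <- learning_config(eta = 0, n_trials = 5)
  b <- suppressWarnings(run_bayes(m, list(c(0.1, 0.3)), cfg, seed = 87))
  # J_E stays equal to J_I, the PC stays at baseline, the integrand vanishes
  expect_lt(max(abs(b$dn_curves[[1]]$dn)), 1e-9)
  expect_equal(b$rescaled[[1]]$t_e, rep(0.2, nrow(b$rescaled[[1]])))
})
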