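test_that("reduced wiring gives every GC 2 drivers + 2 supporters, distinct", {
  reg <- builtin_registry("table3")
  spec <- builtin_rate_spec("reduced-reference")
  for (seed in 1:4) {
    groups <- assign_mf_groups(spec, 30)
    conn <- build_connectivity(30, 200, groups, reg, "reduced", seed = seed)
    lab <- matrix(reg$group_id[groups[conn]], nrow(conn))
    expect_true(all(rowSums(lab == "driver") == 2))
    expect_true(all(rowSums(lab == "supporter") == 2))
    expect_true(all(apply(conn, 1, function(r) length(unique(r)) == 4)))
  }
})

test_that("full wiring honors the required-group constraint", {
  reg <- builtin_registry("table1")
  spec <- builtin_rate_spec("table2")
  groups <- assign_mf_groups(spec, 100)
  req <- reg$group_id[groups] %in% c("1", "2", "5")
  for (seed in 1:4) {
    conn <- build_connectivity(100, 500, groups, reg, "full", seed = seed)
    expect_true(all(rowSums(matrix(req[conn], nrow(conn))) >= 1))
    expect_true(all(apply(conn, 1, function(r) length(unique(r)) == 4)))
  }
})

test_that("synapse-group frequencies match the conditional law", {
  # brute-force oracle: unconditional 4-of-n_mf draws, rejecting those with
  # no required-group fiber, independently of the package's sampler
  reg <- builtin_registry("table1")
  spec <- builtin_rate_spec("table2")
  groups <- assign_mf_groups(spec, 100)
  req <- reg$group_id[groups] %in% c("1", "2", "5")
  set.seed(99)
  n_mc <- 4e4
  draws <- replicate(n_mc, sample.int(100, 4))
  keep <- colSums(matrix(req[draws], 4)) >= 1
  oracle_freq <- tabulate(groups[draws[, keep]], 5) / (4 * sum(keep))

  conn <- build_connectivity(100, 10000, groups, reg, "full", seed = 5)
  freq <- tabulate(groups[conn], 5) / length(conn)
  se <- sqrt(oracle_freq * (1 - oracle_freq) / (4 * 10000))
  expect_true(all(abs(freq - oracle_freq) < 5 * se + 0.002))
})

test_that("degenerate four-fiber wiring is deterministic", {
  reg <- builtin_registry("table3")
  groups <- c(1L, 1L, 2L, 2L)  # two drivers, two supporters
  conn <- build_connectivity(4, 50, groups, reg, "reduced", seed = 1)
  expect_true(all(apply(conn, 1, sort) == c(1, 2, 3, 4)))
})

test_that("calibration hits rate and sparsity targets out of sample", {
  m <- small_full_model()
  fresh <- sample_mf_pattern(m$rate_spec, m$mf_groups, 800, seed = 61)
  r <- gc_steady_rates(m, fresh)
  expect_equal(mean(r), 5, tolerance = 0.03)
  expect_equal(mean(r > 0), 0.2, tolerance = 0.1)
  expect_length(m$calibration$degenerate, 0)
})

test_that("recalibration restores targets after rescaling all MF rates", {
  spec2 <- builtin_rate_spec("table2")
  spec2$mean <- spec2$mean * 2
  spec2$sd <- spec2$sd * 2
  spec2 <- mf_rate_spec(spec2$group_id, spec2$dist, spec2$mean, spec2$sd,
                        occurrence = spec2$occurrence)
  m2 <- circuit_model(builtin_registry("table1"), spec2,
                      n_mf = 100, n_gc = 300, seed = 21)
  m2 <- calibrate_gc(m2, n_patterns = 800, seed = 62)
  fresh <- sample_mf_pattern(spec2, m2$mf_groups, 500, seed = 63)
  r <- gc_steady_rates(m2, fresh)
  expect_equal(mean(r), 5, tolerance = 0.04)
  expect_equal(mean(r > 0), 0.2, tolerance = 0.1)
})

test_that("balanced weights pin the PC at its 40 Hz baseline exactly", {
  m <- tiny_full_model()
  pats <- sample_mf_pattern(m$rate_spec, m$mf_groups, 2, seed = 64)
  tr <- simulate_circuit(m, mf_schedule(pats, c(0.05, 0.2)))
  expect_equal(tr$pc, rep(40, length(tr$pc)), tolerance = 1e-12)
})

test_that("constant schedule from steady-state init stays constant", {
  m <- tiny_full_model()
  pat <- sample_mf_pattern(m$rate_spec, m$mf_groups, 1, seed = 65)
  tr <- simulate_circuit(m, mf_schedule(pat, 0.3))
  expect_lt(diff(range(tr$mli)), 1e-6)
  expect_lt(max(abs(sweep(tr$gc, 2, tr$gc[1, ]))), 1e-4)
})

test_that("MLI equals the GC population mean at every step", {
  m <- tiny_full_model()
  pats <- sample_mf_pattern(m$rate_spec, m$mf_groups, 2, seed = 66)
  tr <- simulate_circuit(m, mf_schedule(pats, 0.1), gc_stride = 10L)
  # block means of the per-step MLI equal GC-block-mean row means
  blk <- matrix(tr$mli, nrow = 10)
  expect_equal(colMeans(blk), unname(rowMeans(tr$gc)), tolerance = 1e-10)
})

test_that("frozen synapses leave only membrane-time-scale transients", {
  m <- tiny_full_model()
  m$J_E <- withr::with_seed(67, rexp(m$n_gc))
  pats <- sample_mf_pattern(m$rate_spec, m$mf_groups, 2, seed = 68)
  sched <- mf_schedule(pats, c(0.1, 0.4))
  tr_on <- simulate_circuit(m, sched)
  tr_off <- simulate_circuit(m, sched, stp_off = TRUE)
  expect_true(tr_off$stp_off)
  # 100 ms after the switch (10 tau_g) the frozen-synapse trace is settled
  idx_late <- tr_off$time > 0.2 & tr_off$time <= 0.5
  expect_lt(diff(range(tr_off$pc[idx_late])), 1e-3)
  # while the STP trace is still relaxing over seconds
  expect_gt(diff(range(tr_on$pc[idx_late])), 0.01)
})

test_that("invalid schedules are rejected", {
  m <- tiny_full_model()
  pat <- sample_mf_pattern(m$rate_spec, m$mf_groups, 1, seed = 69)
  expect_error(simulate_circuit(m, mf_schedule(pat, 0.10037)), "multiples")
  expect_error(mf_schedule(pat, -1), "positive")
  m2 <- m; m2$gain <- rep(NA_real_, m$n_gc)
  expect_error(simulate_circuit(m2, mf_schedule(pat, 0.1)), "not calibrated")
})
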