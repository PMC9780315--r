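cfg_default <- learning_config(n_trials = 50)

test_that("target construction: one zero bin, normalized loss weight", {
  tgt <- make_target(0.2, cfg_default)
  g_bins <- length(tgt$I_target)
  expect_equal(g_bins, 300)
  expect_equal(sum(tgt$I_target == 0), 1)
  expect_equal(tgt$I_target[tgt$target_bin], 0)
  # the zero bin contains t_target
  expect_lt(abs(tgt$time[tgt$target_bin] - 0.2), 0.0025 + 1e-12)
  bin_dt <- 5e-3
  expect_equal(sum(tgt$w_err_tilde * bin_dt), 1, tolerance = 1e-12)
  # flat weighting when the peak is 1
  cfg_flat <- learning_config(w_err_peak = 1)
  tflat <- make_target(0.2, cfg_flat)
  expect_equal(tflat$w_err_tilde, rep(1 / 1.5, 300))
  expect_error(make_target(1.6, cfg_default), "inside")
  expect_error(make_target(0, cfg_default), "inside")
})

test_that("climbing-fiber rate is a rectified affine map of the error", {
  expect_equal(cf_rate(0, 1, 0.5), 1)
  expect_equal(cf_rate(-4, 1, 0.5), 0)
  eps <- seq(-1.5, 10, by = 0.5)
  cf <- cf_rate(eps, 1, 0.5)
  expect_equal(cf - 1, 0.5 * eps, tolerance = 1e-12)  # unrectified branch
})

test_that("weight update vanishes for zero error and silent cells", {
  set.seed(42)
  gc_sub <- matrix(runif(300 * 20, 0, 30), 300, 20)
  gc_sub[, 7] <- 0
  tgt <- make_target(0.3, cfg_default)
  dJ0 <- weight_update(gc_sub, rep(0, 300), tgt, cfg_default)
  expect_equal(dJ0, rep(0, 20))
  dJ <- weight_update(gc_sub, rnorm(300), tgt, cfg_default)
  expect_equal(dJ[7], 0)
  expect_error(weight_update(gc_sub, rnorm(10), tgt, cfg_default), "lengths")
})

test_that("unrectified update equals the loss gradient (finite differences)", {
  # toy network, errors kept small enough that the CF never rectifies;
  # the size-invariant update is -eta*beta*N times dE/dJ
  set.seed(1)
  N <- 20
  cfg <- cfg_default
  gc_sub <- matrix(runif(300 * N, 0, 5), 300, N)
  tgt <- make_target(0.5, cfg)
  J <- runif(N, 9, 11)
  drive <- stptiming:::pc_drive(gc_sub, J, cfg$J_init, cfg$I_spont)
  target <- tgt
  target$I_target <- drive - runif(300, -1, 1)  # |eps| < 2 everywhere
  eps <- drive - target$I_target
  expect_true(all(cf_rate(eps, cfg$cf_spont, cfg$beta) > 0))
  dJ <- weight_update(gc_sub, eps, target, cfg)
  bin_dt <- cfg$dt * cfg$subsample_factor
  loss_of <- function(Jv) {
    d <- stptiming:::pc_drive(gc_sub, Jv, cfg$J_init, cfg$I_spont)
    0.5 * sum(bin_dt * target$w_err_tilde^2 * (d - target$I_target)^2)
  }
  h <- 1e-4
  grad_fd <- vapply(seq_len(N), function(i) {
    Jp <- J; Jp[i] <- J[i] + h
    Jm <- J; Jm[i] <- J[i] - h
    (loss_of(Jp) - loss_of(Jm)) / (2 * h)
  }, numeric(1))
  expect_equal(dJ, -cfg$eta * cfg$beta * N * grad_fd, tolerance = 1e-4)
})

test_that("depression/potentiation signs follow the plasticity rule", {
  cfg <- cfg_default
  gc_sub <- matrix(0, 300, 2)
  gc_sub[150, 1] <- 10           # GC 1 active while CF is above baseline
  gc_sub[250, 2] <- 10           # GC 2 active while CF is silent
  tgt <- make_target(0.3, cfg)
  eps <- rep(0, 300)
  eps[150] <- 20                 # cf = 11 > cf_spont
  eps[250] <- -10                # cf = 0
  dJ <- weight_update(gc_sub, eps, tgt, cfg)
  expect_lt(dJ[1], 0)
  expect_gt(dJ[2], 0)
})

test_that("training respects trivial limits and the weight floor", {
  basis <- small_basis()
  cfg0 <- learning_config(eta = 0, n_trials = 20)
  res0 <- train_readout(basis, cfg0, make_target(0.2, cfg0))
  expect_equal(res0$J_E, rep(10, ncol(basis)))
  expect_equal(diff(range(res0$loss)), 0)

  cfg <- learning_config(n_trials = 300, snapshot_every = 100)
  res <- train_readout(basis, cfg, make_target(0.2, cfg))
  expect_true(all(res$J_E >= 0))
  expect_true(all(res$snapshots >= 0))
  expect_equal(nrow(res$snapshots), 3)
  # descent: training reduces the loss
  expect_lt(res$loss[length(res$loss)], res$loss[1])
})

test_that("loss descends across pattern realizations", {
  m <- small_full_model()
  cfg <- learning_config(n_trials = 200)
  drops <- vapply(1:3, function(s) {
    pats <- sample_mf_pattern(m$rate_spec, m$mf_groups, 2, seed = 70 + s)
    basis <- gc_basis(m, pats[, 1], pats[, 2], cfg)
    res <- train_readout(basis, cfg, make_target(0.15, cfg))
    res$loss[length(res$loss)] < res$loss[1]
  }, logical(1))
  expect_true(all(drops))
})
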