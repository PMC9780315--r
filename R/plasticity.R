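# Climbing-fiber-gated supervised learning of GC->PC weights. The loss is a
# weighted least-squares deviation of the PC drive from a target with a
# single zero bin at the desired pause time; the weight update is the
# gradient filtered through a rectified climbing-fiber rate, with Nesterov
# momentum and adaptive restart on top.

#' Learning-rule configuration
#'
#' @param eta Learning rate (0.0025).
#' @param beta Climbing-fiber gain on the error (0.5).
#' @param cf_spont Spontaneous climbing-fiber rate (Hz; 1 for eyelid
#'   conditioning, 5 for the long interval priors).
#' @param T_pre Pre-stimulus window length (s, 0.1).
#' @param T_CS Stimulus window length (s, 1.4).
#' @param w_err_peak Loss-weight multiplier on the target bin (3.5).
#' @param subsample_factor GC-trace subsampling factor relative to the Euler
#'   grid (10: 5 ms learning bins at dt = 0.5 ms).
#' @param n_trials Number of learning trials.
#' @param J_init Initial GC-PC weight, also the MLI-PC weight (10).
#' @param I_spont PC baseline drive (40 Hz).
#' @param dt Euler step of the underlying simulation (s).
#' @param snapshot_every Record the weight vector every this many trials
#'   (0 = never).
#' @param restart_tol Relative loss-increase tolerance of the adaptive
#'   momentum restart (see [train_readout()]).
#' @param seed Optional seed (used where a task draws per-trial targets).
#' @return A list of class `learning_config`.
#' @export
learning_config <- function(eta = 0.0025, beta = 0.5, cf_spont = 1,
                            T_pre = 0.1, T_CS = 1.4, w_err_peak = 3.5,
                            subsample_factor = 10L, n_trials = 1000L,
                            J_init = 10, I_spont = 40, dt = 5e-4,
                            snapshot_every = 0L, restart_tol = 1e-4,
                            seed = NULL) {
  stopifnot_scalar(eta, "eta", lo = 0)
  stopifnot_scalar(J_init, "J_init", lo = 0)
  if (subsample_factor < 1) stop("subsample_factor must be >= 1",
                                 call. = FALSE)
  structure(list(eta = eta, beta = beta, cf_spont = cf_spont, T_pre = T_pre,
                 T_CS = T_CS, w_err_peak = w_err_peak,
                 subsample_factor = as.integer(subsample_factor),
                 n_trials = as.integer(n_trials), J_init = J_init,
                 I_spont = I_spont, dt = dt,
                 snapshot_every = as.integer(snapshot_every),
                 restart_tol = restart_tol, seed = seed),
            class = "learning_config")
}

learn_grid <- function(config) {
  bin_dt <- config$dt * config$subsample_factor
  n_bins <- round((config$T_pre + config$T_CS) / bin_dt)
  list(bin_dt = bin_dt, n_bins = as.integer(n_bins),
       time = -config$T_pre + (seq_len(n_bins) - 0.5) * bin_dt)
}

#' Build the learning target for one pause time
#'
#' The target PC drive equals the baseline everywhere except in the single
#' subsampled bin containing `t_target` (time measured from stimulus onset),
#' where it is zero. The loss weight is `w_err_peak` in that bin and 1
#' elsewhere, normalized by its discrete integral over the whole window so
#' that `sum(w_err_tilde * bin_dt) = 1`.
#'
#' @param t_target Pause time after stimulus onset (s), in `(0, T_CS)`.
#' @param config A [learning_config()].
#' @return A list of class `target_signal`: `time` (bin centers, s, 0 at
#'   stimulus onset), `I_target` (Hz), `w_err_tilde` (1/s), `t_target`,
#'   `target_bin`.
#' @export
make_target <- function(t_target, config) {
  if (t_target <= 0 || t_target >= config$T_CS)
    stop("t_target must lie inside (0, T_CS)", call. = FALSE)
  g <- learn_grid(config)
  bin <- min(g$n_bins, 1L + floor((t_target + config$T_pre) / g$bin_dt))
  I_target <- rep(config$I_spont, g$n_bins)
  I_target[bin] <- 0
  w <- rep(1, g$n_bins)
  w[bin] <- config$w_err_peak
  structure(list(time = g$time, I_target = I_target,
                 w_err_tilde = w / sum(w * g$bin_dt),
                 t_target = t_target, target_bin = bin),
            class = "target_signal")
}

#' Climbing-fiber rate driven by the error signal
#'
#' `cf = max(cf_spont + beta * epsilon, 0)` with
#' `epsilon = I_pc - I_target`. The rectification limits how much
#' below-baseline error can be signalled.
#'
#' @param epsilon Error trace (Hz).
#' @param cf_spont Spontaneous CF rate (Hz).
#' @param beta Error gain.
#' @return CF rate trace (Hz).
#' @export
cf_rate <- function(epsilon, cf_spont, beta) {
  pmax(cf_spont + beta * epsilon, 0)
}

# PC input (unrectified drive) on the learning grid for a weight vector.
pc_drive <- function(gc_sub, J, J_I, I_spont) {
  as.vector(gc_sub %*% (J - J_I)) / ncol(gc_sub) + I_spont
}

loss_value <- function(I_pc, target, bin_dt) {
  0.5 * sum(bin_dt * target$w_err_tilde^2 * (I_pc - target$I_target)^2)
}

#' One climbing-fiber weight update
#'
#' Discrete quadrature (Riemann sum times bin width) of
#' `dJ_i = eta * integral w_err_tilde^2 (cf_spont - cf(t)) gc_i(t) dt`
#' over the learning window. When the CF rate never rectifies this equals
#' the pure gradient step `-(eta beta) integral w^2 epsilon gc dt`, i.e.
#' `-eta beta N` times the gradient of the loss with respect to `J_i` (the
#' readout averages over the N granule cells, so the size-invariant update
#' carries no 1/N: per-trial progress of the PC rate is then independent of
#' network size, which is what makes a fixed trial budget meaningful across
#' model sizes). Clipping of negative weights is applied by the caller after
#' the momentum step, not here.
#'
#' @param gc_sub `n_bins x N` block-averaged GC traces (Hz).
#' @param epsilon Error trace on the same grid (Hz).
#' @param target A `target_signal` (supplies `w_err_tilde`).
#' @param config A `learning_config`.
#' @return Weight increment vector of length `N`.
#' @export
weight_update <- function(gc_sub, epsilon, target, config) {
  if (nrow(gc_sub) != length(epsilon) ||
      length(epsilon) != length(target$w_err_tilde))
    stop("trace lengths do not match the learning grid", call. = FALSE)
  bin_dt <- config$dt * config$subsample_factor
  cf <- cf_rate(epsilon, config$cf_spont, config$beta)
  kern <- bin_dt * target$w_err_tilde^2 * (config$cf_spont - cf)
  config$eta * as.vector(crossprod(gc_sub, kern))
}

#' Train the GC->PC readout on a fixed granule-cell basis
#'
#' Iterates: PC drive from current weights, error against the trial's
#' target, climbing-fiber rate, weight update -- with Nesterov momentum
#' (coefficient `(k - 1)/(k + 2)`) and adaptive restart: the momentum
#' counter resets whenever the trial loss exceeds the best loss since the
#' last restart by more than the relative tolerance `restart_tol`. (The
#' rectified climbing-fiber rate makes the loss chatter at the 1e-6 relative
#' level near its attractor; an exact-comparison restart would fire on that
#' chatter and freeze the momentum the small learning rate depends on.)
#' Weights are clipped at zero after the momentum step and after the update,
#' so `J_E >= 0` holds at every iteration. Loss values use the same discrete
#' quadrature as the update.
#'
#' @param gc_sub `n_bins x N` block-averaged GC traces over the learning
#'   window (from [simulate_circuit()]).
#' @param config A [learning_config()].
#' @param target A single `target_signal`, or a function `trial -> target`
#'   for tasks whose target varies across trials.
#' @param J_I MLI-PC weight (defaults to `config$J_init`).
#' @return A list of class `learning_result`: `J_E` (final weights), `loss`
#'   (per-trial), `snapshots` (optional weight matrix), `config`.
#' @export
train_readout <- function(gc_sub, config, target, J_I = config$J_init) {
  N <- ncol(gc_sub)
  g <- learn_grid(config)
  if (nrow(gc_sub) != g$n_bins)
    stop("gc_sub rows must equal the number of learning bins", call. = FALSE)
  target_fn <- if (is.function(target)) target else function(trial) target
  J <- rep(config$J_init, N)
  J_prev <- J
  k <- 1L
  loss <- numeric(config$n_trials)
  snaps <- NULL
  if (config$snapshot_every > 0)
    snaps <- matrix(NA_real_, ceiling(config$n_trials /
                                        config$snapshot_every), N)
  E_best <- Inf
  E_init <- NA_real_
  for (trial in seq_len(config$n_trials)) {
    tgt <- target_fn(trial)
    mu <- (k - 1) / (k + 2)
    y <- pmax(J + mu * (J - J_prev), 0)
    I_pc <- pc_drive(gc_sub, y, J_I, config$I_spont)
    eps <- I_pc - tgt$I_target
    dJ <- weight_update(gc_sub, eps, tgt, config)
    J_new <- pmax(y + dJ, 0)
    E <- loss_value(pc_drive(gc_sub, J_new, J_I, config$I_spont), tgt,
                    g$bin_dt)
    if (is.na(E_init)) E_init <- E
    if (E > E_best * (1 + config$restart_tol)) {
      k <- 1L
      E_best <- E
    } else {
      k <- k + 1L
      E_best <- min(E_best, E)
    }
    if (is.finite(E_init) && E > 1e3 * max(E_init, 1e-12))
      stop(sprintf("learning diverged at trial %d (loss %.3g vs initial %.3g)",
                   trial, E, E_init), call. = FALSE)
    loss[trial] <- E
    J_prev <- J
    J <- J_new
    if (config$snapshot_every > 0 && trial %% config$snapshot_every == 0)
      snaps[trial %/% config$snapshot_every, ] <- J
  }
  structure(list(J_E = J, loss = loss, snapshots = snaps, config = config),
            class = "learning_result")
}

#' Simulate the learning-window granule-cell basis for a stimulus switch
#'
#' Runs the circuit for `T_pre` seconds at the pre-stimulus pattern followed
#' by `T_CS` seconds at the stimulus pattern and returns the block-averaged
#' GC traces on the learning grid.
#'
#' @param model A calibrated `circuit_model`.
#' @param m_pre,m_cs Rate vectors (length `n_mf`) before and during the
#'   stimulus.
#' @param config A `learning_config`.
#' @param stp_off Freeze synapse dynamics (removes the temporal basis).
#' @return `n_bins x n_gc` matrix of GC rates (Hz).
#' @export
gc_basis <- function(model, m_pre, m_cs, config, stp_off = FALSE) {
  sched <- mf_schedule(cbind(m_pre, m_cs), c(config$T_pre, config$T_CS))
  tr <- simulate_circuit(model, sched, dt = config$dt, stp_off = stp_off,
                         record_gc = TRUE,
                         gc_stride = config$subsample_factor)
  tr$gc
}
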