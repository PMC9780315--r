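# The three protocol drivers: pattern-switch transients, delay eyelid
# conditioning, and Bayesian time-interval estimation.

pc_steady <- function(model, pattern) {
  gc_ss <- gc_steady_rates(model, matrix(pattern, ncol = 1))[, 1]
  max(mean((model$J_E - model$J_I) * gc_ss) + model$I_spont, 0)
}

#' Pattern-switch transients
#'
#' Presents a chain of MF patterns, re-drawn every `period` seconds with
#' underlying correlation `c` between successive patterns, and measures the
#' steady-state-subtracted PC transient at each switch. GC-PC weights are
#' randomized (exponential, mean `J_E_mean`) so individual GC transients do
#' not cancel at the PC.
#'
#' @param model A calibrated `circuit_model`.
#' @param n_switches Number of pattern switches.
#' @param period Pattern duration (s).
#' @param c Correlation of successive underlying patterns in `[0, 1]`.
#' @param J_E_mean Mean of the exponential GC-PC weight distribution.
#' @param J_I MLI-PC weight.
#' @param dt Euler step (s).
#' @param stp_off Freeze synapse dynamics.
#' @param record_gc Keep block-averaged GC traces in the returned trace.
#' @param seed Seed (weights, patterns).
#' @return A list: `trace` (`trial_trace`), `amplitudes` (per-switch peak
#'   deviation of the PC rate from the segment's settled tail, Hz),
#'   `sd_amplitude`, `c`, `pc_steady` (analytic steady-state PC rate per
#'   segment).
#' @export
run_pattern_switch <- function(model, n_switches = 10, period = 1, c = 0,
                               J_E_mean = 1, J_I = 1, dt = 5e-4,
                               stp_off = FALSE, record_gc = FALSE,
                               seed = NULL) {
  model$J_E <- with_seed(child_seed(seed, 1),
                         rexp(model$n_gc, rate = 1 / J_E_mean))
  model$J_I <- J_I
  patterns <- sample_correlated_patterns(model$rate_spec, model$mf_groups,
                                         n_switches + 1, c,
                                         seed = child_seed(seed, 2))
  sched <- mf_schedule(patterns, period)
  tr <- simulate_circuit(model, sched, dt = dt, stp_off = stp_off,
                         record_gc = record_gc)
  steps_per <- round(period / dt)
  pc_ss <- vapply(seq_len(n_switches + 1), function(s)
    pc_steady(model, patterns[, s]), numeric(1))
  # transient amplitude relative to the settled tail of each segment (valid
  # for both live and frozen synapses, whose steady states differ)
  amps <- vapply(seq_len(n_switches), function(s) {
    idx <- (s * steps_per + 1):((s + 1) * steps_per)
    tail_ref <- mean(tr$pc[idx[idx > max(idx) - max(steps_per %/% 20, 1)]])
    max(abs(tr$pc[idx] - tail_ref))
  }, numeric(1))
  list(trace = tr, amplitudes = amps, sd_amplitude = stats::sd(amps),
       c = c, pc_steady = pc_ss)
}

#' Normalized transient variability across pattern correlations
#'
#' Runs [run_pattern_switch()] for each correlation level and returns the
#' standard deviation of PC transient amplitudes, normalized to the first
#' (typically `c = 0`) level.
#'
#' @inheritParams run_pattern_switch
#' @param c_values Correlation levels to scan.
#' @return Data frame with `c`, `sd_amplitude`, `normalized_sd`.
#' @export
pattern_switch_scan <- function(model, c_values = c(0, 0.5, 0.85, 1),
                                n_switches = 10, period = 1, seed = NULL,
                                dt = 5e-4) {
  sds <- vapply(seq_along(c_values), function(i)
    run_pattern_switch(model, n_switches, period, c_values[i], dt = dt,
                       seed = child_seed(seed, i))$sd_amplitude,
    numeric(1))
  data.frame(c = c_values, sd_amplitude = sds,
             normalized_sd = sds / sds[1])
}

#' Classify granule cells as slow or fast from their transient decay
#'
#' Decay times to 10% of the transient peak are computed from
#' steady-state-subtracted basis traces (steady state taken as the mean of
#' the last tenth of the window); cells at or above `threshold` are "slow".
#'
#' @param basis `n_bins x n_gc` GC traces over the learning window.
#' @param bin_dt Bin width (s).
#' @param threshold Decay-time split point (s).
#' @return List with `decay_times` (s, `NA` where undefined), `slow`,
#'   `fast` (index vectors).
#' @export
classify_gc_speed <- function(basis, bin_dt, threshold = 0.15) {
  n <- nrow(basis)
  tail_rows <- max(1, round(0.1 * n))
  ss <- colMeans(basis[(n - tail_rows + 1):n, , drop = FALSE])
  dts <- vapply(seq_len(ncol(basis)), function(i)
    decay_time_to_10pct(basis[, i] - ss[i], bin_dt), numeric(1))
  list(decay_times = dts,
       slow = which(!is.na(dts) & dts >= threshold),
       fast = which(is.na(dts) | dts < threshold))
}

#' Delay eyelid conditioning
#'
#' For each conditioned-stimulus/unconditioned-stimulus delay: trains the
#' GC-PC readout against a pause target at that delay on the granule-cell
#' basis evoked by an instantaneous persistent MF pattern switch, then
#' evaluates the learned PC trace and its pause metrics. Evaluation traces
#' are averaged over `realizations` independent MF-pattern draws (seeds
#' `seed + 0 .. realizations - 1`) before metric extraction.
#'
#' @param model A calibrated `circuit_model`.
#' @param delays Target delays after stimulus onset (s).
#' @param config A [learning_config()].
#' @param realizations Number of MF-pattern realizations averaged.
#' @param gc_mask Optional GC indices whose basis traces are zeroed
#'   (subset-ablation experiments).
#' @param stp_off Freeze synapse dynamics (no temporal basis).
#' @param seed Seed.
#' @return A list of class `eyelid_result`: `time` (learning-grid bin
#'   centers, s), `pc` (`n_bins x n_delays` trial-averaged learned traces),
#'   `metrics` (list of `pause_metrics`), `delays`, `loss` (final-trial
#'   loss per delay, averaged).
#' @export
run_eyelid <- function(model, delays, config, realizations = 1,
                       gc_mask = NULL, stp_off = FALSE, seed = NULL) {
  g <- learn_grid(config)
  pc_acc <- matrix(0, g$n_bins, length(delays))
  loss_acc <- numeric(length(delays))
  for (r in seq_len(realizations)) {
    rseed <- if (is.null(seed)) NULL else seed + r - 1
    pats <- sample_mf_pattern(model$rate_spec, model$mf_groups, 2,
                              seed = rseed)
    basis <- gc_basis(model, pats[, 1], pats[, 2], config,
                      stp_off = stp_off)
    if (!is.null(gc_mask)) basis[, gc_mask] <- 0
    for (d in seq_along(delays)) {
      tgt <- make_target(delays[d], config)
      res <- train_readout(basis, config, tgt)
      pc_acc[, d] <- pc_acc[, d] +
        pmax(pc_drive(basis, res$J_E, config$J_init, config$I_spont), 0)
      loss_acc[d] <- loss_acc[d] + res$loss[length(res$loss)]
    }
  }
  pc <- pc_acc / realizations
  metrics <- lapply(seq_along(delays), function(d)
    pause_metrics(pc[, d], g$time, delays[d],
                  window = c(0, config$T_CS)))
  structure(list(time = g$time, pc = pc, metrics = metrics, delays = delays,
                 loss = loss_acc / realizations),
            class = "eyelid_result")
}

#' Bayesian time-interval estimation
#'
#' For each uniform prior: trains the readout with the per-trial pause
#' target drawn from the prior (the network's own temporal basis plays the
#' role of the noisy measurement), evaluates the trial-averaged learned PC
#' trace, integrates the downstream dentate-nucleus unit
#' `dn(t) = integral (I_ext - J_pc pc) dt` with `I_ext` equal to the mean PC
#' rate over the prior window, rescales each DN curve affinely so its
#' extrema map onto the prior bounds, and finally fits a single Weber
#' fraction to all rescaled curves jointly against the BLS estimator.
#'
#' The spontaneous climbing-fiber rate is raised to `cf_spont_long` for
#' priors starting at or above `long_prior_lo` (the longer intervals need a
#' stronger depression bias).
#'
#' @param model A calibrated `circuit_model`.
#' @param priors List of `c(lo, hi)` uniform prior supports (s).
#' @param config A [learning_config()].
#' @param realizations MF-pattern realizations averaged per prior.
#' @param J_pc PC-to-DN inhibitory weight.
#' @param cf_spont_long,long_prior_lo CF baseline override for long priors.
#' @param i_ext_mode Window over which the DN excitatory drive `I_ext` is
#'   the mean PC rate: `"interval"` (the prior support) or `"trace"` (the
#'   whole post-onset trace; more robust when the learned suppression is
#'   concentrated early in the window).
#' @param seed Seed.
#' @return A list of class `bayes_result`: `priors`, `time`, `pc`
#'   (`n_bins x n_priors`), `dn_curves`/`rescaled` (per-prior data frames),
#'   `fit` (from [fit_weber()]).
#' @export
run_bayes <- function(model, priors, config, realizations = 1, J_pc = 1,
                      cf_spont_long = 5, long_prior_lo = 0.2,
                      i_ext_mode = c("interval", "trace"), seed = NULL) {
  i_ext_mode <- match.arg(i_ext_mode)
  g <- learn_grid(config)
  pc <- matrix(0, g$n_bins, length(priors))
  dn_curves <- vector("list", length(priors))
  rescaled <- vector("list", length(priors))
  for (p in seq_along(priors)) {
    pr <- priors[[p]]
    cfg <- config
    if (pr[1] >= long_prior_lo) cfg$cf_spont <- cf_spont_long
    t_targets <- with_seed(child_seed(seed, 100 + p),
                           runif(cfg$n_trials, pr[1], pr[2]))
    target_fn <- function(trial) make_target(t_targets[trial], cfg)
    for (r in seq_len(realizations)) {
      rseed <- if (is.null(seed)) NULL else seed + r - 1
      pats <- sample_mf_pattern(model$rate_spec, model$mf_groups, 2,
                                seed = rseed)
      basis <- gc_basis(model, pats[, 1], pats[, 2], cfg)
      res <- train_readout(basis, cfg, target_fn)
      pc[, p] <- pc[, p] +
        pmax(pc_drive(basis, res$J_E, cfg$J_init, cfg$I_spont), 0)
    }
    pc[, p] <- pc[, p] / realizations
    win <- which(g$time >= pr[1] & g$time <= pr[2])
    post <- which(g$time >= 0)
    I_ext <- if (i_ext_mode == "interval") mean(pc[win, p])
             else mean(pc[post, p])
    dn_full <- cumsum((I_ext - J_pc * pc[post, p]) * g$bin_dt)
    dn <- dn_full[match(win, post)]
    if (any(diff(dn) < 0))
      warning("DN output not monotone over the prior window", call. = FALSE)
    dn_min <- min(dn); dn_max <- max(dn)
    t_hat <- if (dn_max > dn_min)
      (pr[2] - pr[1]) * (dn - dn_min) / (dn_max - dn_min) + pr[1]
    else rep(mean(pr), length(dn))
    dn_curves[[p]] <- data.frame(t = g$time[win], dn = dn)
    rescaled[[p]] <- data.frame(t_m = g$time[win], t_e = t_hat)
  }
  fit <- fit_weber(rescaled, priors)
  structure(list(priors = priors, time = g$time, pc = pc,
                 dn_curves = dn_curves, rescaled = rescaled, fit = fit),
            class = "bayes_result")
}
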