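# Quantitative readouts: GC transient decay times, learned-pause error,
# Bayesian least-squares interval estimation and the Weber-fraction fit,
# and the joint transient-amplitude / time-constant density.

#' Decay time of a transient to 10% of its peak
#'
#' For a steady-state-subtracted trace, returns the time from the absolute
#' peak to the first subsequent crossing of `frac` times the absolute peak,
#' linearly interpolated between samples. Returns `NA` (flagged undefined)
#' for flat traces or traces that never decay below the threshold.
#'
#' @param trace Steady-state-subtracted trace (numeric vector).
#' @param dt Sample spacing (s).
#' @param frac Threshold fraction of the absolute peak (0.1).
#' @return Decay time (s), or `NA_real_` if undefined.
#' @export
decay_time_to_10pct <- function(trace, dt, frac = 0.1) {
  a <- abs(trace)
  pk <- which.max(a)
  peak <- a[pk]
  if (peak <= 0) return(NA_real_)
  thr <- frac * peak
  after <- a[pk:length(a)]
  below <- which(after < thr)
  if (!length(below)) return(NA_real_)
  k <- below[1]
  if (k == 1L) return(0)
  # linear interpolation between samples k-1 (>= thr) and k (< thr)
  f <- (after[k - 1] - thr) / (after[k - 1] - after[k])
  (k - 2 + f) * dt
}

#' Quantify a learned Purkinje-cell pause
#'
#' Baseline `h_spont` is the mean rate over the pre-stimulus window
#' (`time < 0`). Amplitude is baseline minus the post-onset minimum; the
#' full width at half maximum is measured by linear interpolation at the
#' half-depth level around the minimum (the minimum itself is taken at the
#' bin minimum); the timing deviation is `|t_min - t_target|`. The total
#' error is `(1 - amplitude/h_spont) + fwhm/s + 5 * eps_t/s` with `s` = 1
#' second.
#'
#' Conventions for degenerate traces: if the trace never dips below
#' baseline, amplitude is 0, the FWHM term is set to the window length and
#' the timing term to 0 (both are undefined); if a half-depth crossing is
#' missing on one side, the window edge is used.
#'
#' @param pc PC rate trace (Hz).
#' @param time Times (s), 0 at stimulus onset, negative in the pre-window.
#' @param t_target Target pause time (s).
#' @param window Post-onset window `c(lo, hi)` to search for the pause
#'   (default the whole post-onset trace).
#' @return A list of class `pause_metrics`: `amplitude` (Hz), `fwhm` (s),
#'   `epsilon_t` (s), `epsilon_tot`, `h_spont`, `t_min`, `fwhm_defined`.
#' @export
pause_metrics <- function(pc, time, t_target, window = NULL) {
  if (length(pc) != length(time)) stop("pc and time lengths differ",
                                       call. = FALSE)
  pre <- time < 0
  if (!any(pre)) stop("trace must include a pre-stimulus window",
                      call. = FALSE)
  h_spont <- mean(pc[pre])
  if (is.null(window)) window <- c(0, max(time))
  sel <- which(time >= window[1] & time <= window[2])
  win_len <- diff(window)
  i_min <- sel[which.min(pc[sel])]
  # degenerate minima (rate clipped at zero over several bins): take the
  # midpoint of the contiguous minimal plateau containing the argmin
  vmin <- pc[i_min]
  tie <- pc[sel] <= vmin + 1e-9 + 1e-9 * abs(h_spont)
  lo <- i_min
  while (lo > sel[1] && tie[match(lo - 1, sel)]) lo <- lo - 1
  hi <- i_min
  while (hi < sel[length(sel)] && tie[match(hi + 1, sel)]) hi <- hi + 1
  t_min <- (time[lo] + time[hi]) / 2
  amplitude <- h_spont - pc[i_min]
  if (amplitude <= 0) {
    out <- list(amplitude = 0, fwhm = win_len, epsilon_t = 0,
                epsilon_tot = 1 + win_len, h_spont = h_spont,
                t_min = NA_real_, fwhm_defined = FALSE)
    class(out) <- "pause_metrics"
    return(out)
  }
  half <- h_spont - amplitude / 2
  cross_time <- function(i1, i2) {  # pc crosses `half` between i1 and i2
    f <- (half - pc[i1]) / (pc[i2] - pc[i1])
    time[i1] + f * (time[i2] - time[i1])
  }
  left <- window[1]
  for (i in rev(sel[sel < i_min])) {
    if (pc[i] >= half) { left <- cross_time(i, i + 1); break }
  }
  right <- window[2]
  for (i in sel[sel > i_min]) {
    if (pc[i] >= half) { right <- cross_time(i - 1, i); break }
  }
  fwhm <- right - left
  eps_t <- abs(t_min - t_target)
  out <- list(amplitude = amplitude, fwhm = fwhm, epsilon_t = eps_t,
              epsilon_tot = (1 - amplitude / h_spont) + fwhm + 5 * eps_t,
              h_spont = h_spont, t_min = t_min, fwhm_defined = TRUE)
  class(out) <- "pause_metrics"
  out
}

#' Bayesian least-squares interval estimate
#'
#' Posterior-mean estimate of the sample interval `t_s` given a noisy
#' measurement `t_m`, under scalar (Weber-law) measurement noise
#' `t_m | t_s ~ N(t_s, (w t_s)^2)` and a uniform prior on
#' `[prior[1], prior[2]]`. Computed by quadrature on a grid no coarser than
#' `grid_dt` over the prior support.
#'
#' @param t_m Measured interval(s) (s, `> 0`).
#' @param prior `c(lo, hi)` prior support (s).
#' @param w Weber fraction (`> 0`).
#' @param grid_dt Quadrature resolution (s, at most 0.1 ms used).
#' @return Estimates `t_e` (s), one per element of `t_m`.
#' @export
bls_estimate <- function(t_m, prior, w, grid_dt = 1e-4) {
  if (any(t_m <= 0)) stop("t_m must be positive", call. = FALSE)
  stopifnot_scalar(w, "w", lo = 1e-12)
  if (prior[2] < prior[1]) stop("prior bounds out of order", call. = FALSE)
  if (prior[2] == prior[1]) return(rep(prior[1], length(t_m)))
  n <- max(ceiling(diff(prior) / min(grid_dt, 1e-4)) + 1, 11)
  ts <- seq(prior[1], prior[2], length.out = n)
  vapply(t_m, function(tm) {
    lik <- dnorm(tm, mean = ts, sd = w * ts)
    s <- sum(lik)
    if (s == 0) {  # posterior mass pinned at the nearer boundary
      return(if (tm < prior[1]) prior[1] else prior[2])
    }
    sum(ts * lik) / s
  }, numeric(1))
}

#' Fit the Weber fraction to rescaled output curves
#'
#' One-dimensional least squares over `w` in `interval`: minimizes the
#' summed squared deviation between the supplied estimate curves (one per
#' prior) and the theoretical BLS estimator with Weber fraction `w`,
#' jointly across all priors. A minimizer at the search boundary triggers a
#' warning.
#'
#' @param curves List of data frames with columns `t_m` and `t_e` (s), one
#'   per prior.
#' @param priors List of `c(lo, hi)` prior supports matching `curves`.
#' @param interval Search bracket for `w`.
#' @return List with `w_weber`, `objective` (total SSE), `sse_per_prior`,
#'   and `boundary` (logical).
#' @export
fit_weber <- function(curves, priors, interval = c(0.01, 0.5)) {
  if (length(curves) != length(priors))
    stop("curves and priors lengths differ", call. = FALSE)
  sse <- function(w) {
    sum(vapply(seq_along(curves), function(i) {
      pred <- bls_estimate(curves[[i]]$t_m, priors[[i]], w)
      sum((curves[[i]]$t_e - pred)^2)
    }, numeric(1)))
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-6)
  w <- opt$minimum
  boundary <- min(w - interval[1], interval[2] - w) < 1e-4
  if (boundary)
    warning("Weber-fraction fit at the search boundary", call. = FALSE)
  per_prior <- vapply(seq_along(curves), function(i) {
    pred <- bls_estimate(curves[[i]]$t_m, priors[[i]], w)
    sum((curves[[i]]$t_e - pred)^2)
  }, numeric(1))
  list(w_weber = w, objective = opt$objective, sse_per_prior = per_prior,
       boundary = boundary)
}

#' Joint distribution of transient amplitude and synaptic time constant
#'
#' Draws `n` independent (pre-switch, post-switch) rate pairs per synapse
#' group from the rate ensemble, evaluates the closed-form transient
#' amplitude and time constant for each vesicle pool, discards samples with
#' zero post-switch rate (no transmission: the transient amplitude vanishes
#' and the time constant is not observable), and returns the samples with
#' marginal and joint kernel-density grids (rule-of-thumb bandwidths; the
#' densities are for export and plotting only).
#'
#' @param rate_spec An `mf_rate_spec` aligned row-by-row with `registry`.
#' @param registry A `synapse_registry` (reduced-model parameters).
#' @param n Rate draws per group.
#' @param seed Optional seed.
#' @param grid_n Density grid size.
#' @return List with `samples` (data frame: `group_id`, `pool`, `m_pre`,
#'   `m`, `A_t`, `tau_syn`), `marginals` (per pool/group `density` objects),
#'   `joint` (per pool/group `kde2d` grids).
#' @export
joint_At_tau_density <- function(rate_spec, registry, n = 1e5, seed = NULL,
                                 grid_n = 101) {
  if (!identical(rate_spec$group_id, registry$group_id))
    stop("registry and rate spec group ids must match", call. = FALSE)
  samples <- with_seed(seed, {
    out <- list()
    for (g in seq_len(nrow(registry))) {
      rates <- sample_mf_pattern(rate_spec, rep(g, n), 2)
      m_pre <- rates[, 1]; m <- rates[, 2]
      keep <- m > 0
      if (!any(keep)) stop("all post-switch rates are zero", call. = FALSE)
      pools <- c(if (registry$N_slow[g] > 0) "slow", "fast")
      for (pool in pools) {
        pv <- if (pool == "slow") registry$p_v_slow[g] else
          registry$p_v_fast[g]
        N <- if (pool == "slow") registry$N_slow[g] else registry$N_fast[g]
        tr <- if (pool == "slow") registry$tau_ref_slow[g] else
          registry$tau_ref_fast[g]
        d <- transient_decomposition(N, pv, m_pre[keep], m[keep], tr,
                                     registry$p_ref[g], pool)
        out[[length(out) + 1]] <-
          data.frame(group_id = registry$group_id[g], pool = pool,
                     m_pre = m_pre[keep], m = m[keep],
                     A_t = d$A_t, tau_syn = d$tau_syn)
      }
    }
    do.call(rbind, out)
  })
  key <- interaction(samples$group_id, samples$pool, drop = TRUE)
  marginals <- lapply(split(samples, key), function(s)
    list(tau_syn = stats::density(s$tau_syn, n = grid_n),
         A_t = stats::density(s$A_t, n = grid_n)))
  joint <- lapply(split(samples, key), function(s) {
    sub <- utils::head(s, 20000)  # i.i.d. rows; cap the kde2d cost
    if (stats::sd(sub$tau_syn) < 1e-12 || stats::sd(sub$A_t) < 1e-12)
      return(NULL)
    MASS::kde2d(sub$tau_syn, sub$A_t, n = grid_n)
  })
  list(samples = samples, marginals = marginals, joint = joint)
}
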