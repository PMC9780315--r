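# Closed-form step-response analytics of a single vesicle pool (reduced
# model): after an instantaneous rate switch m_pre -> m, the synaptic current
# relaxes mono-exponentially, I(t) = A_s + A_t exp(-t / tau_syn).

pool_alpha <- function(tau_ref, p_ref, pool) {
  switch(pool, slow = tau_ref * (1 - p_ref), fast = tau_ref,
         stop("pool must be 'slow' or 'fast'", call. = FALSE))
}

#' Synaptic relaxation time constant of a vesicle pool
#'
#' `tau_syn = tau_ref / (1 + alpha p_v m)` with `alpha = tau_ref (1 - p_ref)`
#' for the slow pool and `alpha = tau_ref` for the fast pool. It is the time
#' constant with which the pool occupancy (and hence the synaptic current)
#' relaxes to steady state after a rate switch to `m`; it decreases with both
#' `m` and `p_v` and is bounded above by `tau_ref` (attained at `m = 0`).
#'
#' @param p_v Release probability in `[0, 1]`.
#' @param m Presynaptic firing rate during the step (Hz, `>= 0`).
#' @param tau_ref Pool refill time constant (s).
#' @param p_ref Immediate-refill probability (slow pool only).
#' @param pool `"slow"` or `"fast"`.
#' @return Time constant(s) in seconds.
#' @export
tau_syn <- function(p_v, m, tau_ref, p_ref = NA, pool = c("slow", "fast")) {
  pool <- match.arg(pool)
  if (any(m < 0)) stop("firing rate m must be non-negative", call. = FALSE)
  if (pool == "slow" && any(is.na(p_ref)))
    stop("p_ref is required for the slow pool", call. = FALSE)
  tau_ref / (1 + pool_alpha(tau_ref, p_ref, pool) * p_v * m)
}

#' Steady-state and transient amplitudes of a pool's step response
#'
#' For a switch from `m_pre` to `m`, the pool's current decomposes into a
#' steady-state amplitude `A_s = N p_v m / (1 + alpha p_v m)` and a signed
#' transient amplitude
#' `A_t = A_s * alpha p_v (m - m_pre) / (1 + alpha p_v m_pre)` that decays
#' with [tau_syn()]. The per-synapse transient is the sum of the slow- and
#' fast-pool transients. `sign(A_t) = sign(m - m_pre)`, and `A_t = A_s = 0`
#' when `m = 0` (no transmission).
#'
#' @param N Number of release sites.
#' @param m_pre Firing rate before the switch (Hz, `>= 0`).
#' @inheritParams tau_syn
#' @return A data frame of class `transient_decomposition` with columns
#'   `A_s`, `A_t`, `tau_syn`, `alpha_eff` (all vectorized).
#' @export
transient_decomposition <- function(N, p_v, m_pre, m, tau_ref, p_ref = NA,
                                    pool = c("slow", "fast")) {
  pool <- match.arg(pool)
  if (any(m < 0) || any(m_pre < 0))
    stop("firing rates must be non-negative", call. = FALSE)
  alpha <- pool_alpha(tau_ref, p_ref, pool)
  A_s <- N * p_v * m / (1 + alpha * p_v * m)
  A_t <- A_s * alpha * p_v * (m - m_pre) / (1 + alpha * p_v * m_pre)
  out <- data.frame(A_s = A_s, A_t = A_t,
                    tau_syn = tau_ref / (1 + alpha * p_v * m),
                    alpha_eff = alpha)
  class(out) <- c("transient_decomposition", "data.frame")
  out
}

#' Evaluate the closed-form step-response current
#'
#' `I(t) = A_s + A_t exp(-t / tau_syn)` for `t >= 0` after the switch.
#'
#' @param decomp A one-row `transient_decomposition`.
#' @param t Times since the switch (s, `>= 0`).
#' @return Current values (vesicle rate units).
#' @export
closed_form_current <- function(decomp, t) {
  if (nrow(decomp) != 1L)
    stop("decomp must be a single decomposition row", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  decomp$A_s + decomp$A_t * exp(-t / decomp$tau_syn)
}
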