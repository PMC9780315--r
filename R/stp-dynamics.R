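# Two-pool vesicle dynamics of the MF-GC synapse.
#
# State variables per connection: x_slow, x_fast (available fraction of each
# readily releasable pool), u_slow, u_fast (effective release probabilities,
# facilitation-modulated), q (normalized quantal size, desensitization).
# All synapses driven by the same mossy fiber share identical trajectories,
# so every function here is vectorized over parameter rows.

expand_params <- function(params, n) {
  p <- as.data.frame(params)
  if (nrow(p) == 1L && n > 1L) p <- p[rep(1L, n), , drop = FALSE]
  if (nrow(p) != n) stop("parameter rows and rate vector lengths differ",
                         call. = FALSE)
  p
}

new_synapse_state <- function(x_slow, x_fast, u_slow, u_fast, q) {
  structure(list(x_slow = x_slow, x_fast = x_fast,
                 u_slow = u_slow, u_fast = u_fast, q = q),
            class = "synapse_state")
}

#' Steady state of the synapse dynamics at a constant firing rate
#'
#' Closed-form fixed point of the vesicle-pool equations under a constant
#' presynaptic rate `m`: facilitated release probabilities
#' `u* = p_v (1 + tau_F m) / (1 + p_v tau_F m)`, pool occupancies
#' `x* = 1 / (1 + u* alpha_eff m)` with `alpha_eff = tau_ref (1 - p_ref)` for
#' the slow pool and `tau_ref` for the fast pool, and desensitized quantal
#' size `q* = q0 N_tot / (N_tot + Delta_D tau_D (n_slow* + n_fast*) m)`.
#'
#' In the reduced model (`model = "reduced"`) release probabilities are the
#' constants `p_v` and `q = 1`; only the occupancies depend on `m`.
#'
#' @param params A `synapse_registry` (or subset of rows), recycled against
#'   `m`.
#' @param m Presynaptic firing rate(s), Hz, `>= 0`.
#' @param model `"full"` or `"reduced"`.
#' @return A `synapse_state`: list of numeric vectors `x_slow`, `x_fast`,
#'   `u_slow`, `u_fast`, `q`. Slow-pool fields are `NA` for groups without a
#'   slow pool (`N_slow = 0`).
#' @export
stp_steady_state <- function(params, m, model = c("full", "reduced")) {
  model <- match.arg(model)
  if (any(m < 0)) stop("firing rate m must be non-negative", call. = FALSE)
  n <- max(length(m), nrow(as.data.frame(params)))
  m <- rep_len(m, n)
  p <- expand_params(params, n)
  has_slow <- p$N_slow > 0
  if (model == "full") {
    tf <- ifelse(is.na(p$tau_F), 0, p$tau_F)
    u_slow <- p$p_v_slow * (1 + tf * m) / (1 + p$p_v_slow * tf * m)
    u_fast <- p$p_v_fast * (1 + tf * m) / (1 + p$p_v_fast * tf * m)
  } else {
    u_slow <- p$p_v_slow
    u_fast <- p$p_v_fast
  }
  x_slow <- 1 / (1 + u_slow * p$tau_ref_slow * (1 - p$p_ref) * m)
  x_fast <- 1 / (1 + u_fast * p$tau_ref_fast * m)
  u_slow[!has_slow] <- NA_real_
  x_slow[!has_slow] <- NA_real_
  if (model == "full" && any(!is.na(p$Delta_D))) {
    n_slow <- ifelse(has_slow, p$N_slow * u_slow * x_slow, 0)
    n_fast <- p$N_fast * u_fast * x_fast
    n_tot <- p$N_slow + p$N_fast
    dd <- ifelse(is.na(p$Delta_D), 0, p$Delta_D)
    td <- ifelse(is.na(p$tau_D), 1, p$tau_D)
    q <- p$q0 * n_tot / (n_tot + dd * td * (n_slow + n_fast) * m)
  } else {
    q <- p$q0
  }
  new_synapse_state(x_slow, x_fast, u_slow, u_fast, rep_len(q, n))
}

#' One explicit-Euler step of the synapse dynamics
#'
#' Advances the five state variables by `dt`. Pool occupancies deplete at the
#' release rate `u x m` (the slow pool at `u (1 - p_ref) x m`, since a
#' fraction `p_ref` of released sites refill immediately) and recover with
#' time constant `tau_ref`; release probabilities facilitate toward 1 at rate
#' `p_v (1 - u) m` and relax back to `p_v` with time constant `tau_F`; the
#' quantal size is depressed in proportion to the released vesicle fraction
#' and recovers with `tau_D`. All variables are clipped to their invariant
#' bounds after the step; a step so large that a variable would overshoot its
#' bounds by more than `clip_tol` raises a warning.
#'
#' With `model = "reduced"` only the occupancies evolve; `u` and `q` are left
#' untouched (they are constants of the reduced model).
#'
#' @param state A `synapse_state`.
#' @inheritParams stp_steady_state
#' @param dt Time step (s), `> 0`.
#' @param clip_tol Tolerated overshoot before warning.
#' @return The updated `synapse_state`.
#' @export
stp_step <- function(state, params, m, dt, model = c("full", "reduced"),
                     clip_tol = 0.01) {
  model <- match.arg(model)
  if (any(m < 0)) stop("firing rate m must be non-negative", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  n <- length(state$x_fast)
  m <- rep_len(m, n)
  p <- expand_params(params, n)
  has_slow <- p$N_slow > 0
  u_slow <- state$u_slow; u_fast <- state$u_fast; q <- state$q
  if (model == "full") {
    tf <- ifelse(is.na(p$tau_F), Inf, p$tau_F)
    u_slow <- u_slow + dt * ((p$p_v_slow - u_slow) / tf +
                               p$p_v_slow * (1 - u_slow) * m)
    u_fast <- u_fast + dt * ((p$p_v_fast - u_fast) / tf +
                               p$p_v_fast * (1 - u_fast) * m)
  }
  x_slow <- state$x_slow + dt *
    ((1 - state$x_slow) / p$tau_ref_slow -
       state$u_slow * (1 - p$p_ref) * state$x_slow * m)
  x_fast <- state$x_fast + dt *
    ((1 - state$x_fast) / p$tau_ref_fast -
       state$u_fast * state$x_fast * m)
  if (model == "full") {
    dd <- ifelse(is.na(p$Delta_D), 0, p$Delta_D)
    td <- ifelse(is.na(p$tau_D), Inf, p$tau_D)
    n_rel <- ifelse(has_slow,
                    p$N_slow * state$u_slow * state$x_slow, 0) +
      p$N_fast * state$u_fast * state$x_fast
    q <- q + dt * ((p$q0 - q) / td -
                     dd * q * n_rel / (p$N_slow + p$N_fast) * m)
  }
  over <- max(0, x_fast - 1, -x_fast, q - p$q0, -q,
              if (any(has_slow)) c(x_slow[has_slow] - 1, -x_slow[has_slow]),
              if (model == "full") c(u_fast - 1, -u_fast,
                                     u_slow[has_slow] - 1, -u_slow[has_slow]),
              na.rm = TRUE)
  if (over > clip_tol)
    warning(sprintf("Euler step left invariant bounds by %.3g; reduce dt",
                    over), call. = FALSE)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  x_slow <- clip01(x_slow); x_slow[!has_slow] <- NA_real_
  u_slow <- clip01(u_slow); u_slow[!has_slow] <- NA_real_
  new_synapse_state(x_slow, clip01(x_fast), u_slow, clip01(u_fast),
                    pmin(pmax(q, 0), p$q0))
}

#' Total synaptic weight of a state
#'
#' `W = q (N_slow u_slow x_slow + N_fast u_fast x_fast)`, in vesicle units.
#' The current per unit time transmitted by the synapse is `W * m`. Groups
#' without a slow pool contribute only the fast-pool term.
#'
#' @inheritParams stp_step
#' @return Numeric vector of weights.
#' @export
synaptic_weight <- function(state, params) {
  n <- length(state$x_fast)
  p <- expand_params(params, n)
  slow <- ifelse(p$N_slow > 0,
                 p$N_slow * state$u_slow * state$x_slow, 0)
  state$q * (slow + p$N_fast * state$u_fast * state$x_fast)
}
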