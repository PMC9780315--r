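# Mean-field treatment of recurrent Golgi-cell inhibition in the reduced
# model. One GoC fires at the GC population mean and inhibits every GC with
# weight J_goc, acting as an activity-dependent threshold. A self-consistent
# (J_goc, gain) pair is found so that the steady state keeps the calibration
# targets (mean GC rate 5 Hz, active fraction 0.2).

# Gaussian-input rectified mean: E[ a * max(mu + sigma*xi - th, 0) ],
# xi ~ N(0,1).
rectified_mean <- function(a, mu, sigma, th) {
  z <- (mu - th) / sigma
  a * ((mu - th) * pnorm(z) + sigma * dnorm(z))
}

#' Self-consistent Golgi feedback weight and common GC gain
#'
#' Starts from a calibrated reduced-mode model, replaces the per-GC gains and
#' thresholds by their population means (the reduced model's GCs all receive
#' the same input combination, so these are nearly homogeneous), reduces the
#' common threshold by 10%, and introduces the GoC loop. Treating the GC
#' steady-state input as Gaussian across patterns with mean
#' `<I> = M - J_goc <gc*>` and standard deviation `sigma` (measured from
#' `n_patterns` fresh patterns; the feedback shifts only the mean), the two
#' mean-field conditions
#' `<gc*> = gain * E[max(<I> + sigma xi - theta_t, 0)] = target_rate` and
#' `f = Phi((<I> - theta_t)/sigma) = sparsity`
#' are solved for `(J_goc, gain)` by damped Newton iteration with numerical
#' Jacobian (residuals below `tol`).
#'
#' @param model A calibrated reduced-mode `circuit_model`.
#' @param n_patterns Patterns used to estimate the input mean and sd.
#' @param target_rate,sparsity Calibration targets (5 Hz, 0.2).
#' @param theta_shrink Factor applied to the common threshold (0.9).
#' @param tol Residual tolerance.
#' @param seed Optional seed.
#' @return A list with `J_goc`, `gain`, `theta` (the reduced common
#'   threshold), `residuals`, `input_mean`, `input_sd`, and `model`: the
#'   input model rewritten with the homogeneous solution (ready for
#'   [golgi_steady_rates()] or [simulate_circuit()]).
#' @export
golgi_self_consistent <- function(model, n_patterns = 1000, target_rate = 5,
                                  sparsity = 0.2, theta_shrink = 0.9,
                                  tol = 1e-8, seed = NULL) {
  if (model$mode != "reduced")
    stop("the mean-field Golgi loop applies to the reduced model",
         call. = FALSE)
  if (all(is.na(model$gain))) stop("model is not calibrated", call. = FALSE)
  theta_t <- theta_shrink * mean(model$threshold)
  gain0 <- mean(model$gain)
  patterns <- sample_mf_pattern(model$rate_spec, model$mf_groups,
                                n_patterns, seed = seed)
  I <- gc_steady_inputs(model, patterns)
  M <- mean(I)
  sigma <- stats::sd(as.vector(I))

  resid <- function(par) {
    J_goc <- par[1]; a <- par[2]
    mu <- M - J_goc * target_rate
    z <- (mu - theta_t) / sigma
    c(rectified_mean(a, mu, sigma, theta_t) - target_rate,
      pnorm(z) - sparsity)
  }
  par <- c(max((M - theta_t - sigma * qnorm(sparsity)) / target_rate, 0.01),
           gain0)
  for (it in 1:100) {
    r <- resid(par)
    if (max(abs(r)) < tol) break
    h <- 1e-7 * pmax(abs(par), 1)
    J <- cbind((resid(par + c(h[1], 0)) - r) / h[1],
               (resid(par + c(0, h[2])) - r) / h[2])
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      if (max(abs(resid(cand))) < max(abs(r)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    par <- par - lambda * step
  }
  r <- resid(par)
  if (max(abs(r)) >= tol)
    stop(sprintf("Golgi mean-field solver did not converge (residuals %g, %g)",
                 r[1], r[2]), call. = FALSE)
  out_model <- model
  out_model$gain <- rep(par[2], model$n_gc)
  out_model$threshold <- rep(theta_t, model$n_gc)
  out_model$J_goc <- par[1]
  list(J_goc = par[1], gain = par[2], theta = theta_t, residuals = r,
       input_mean = M, input_sd = sigma, model = out_model)
}

# Population-mean GC rate for one pattern: unique root of the monotone
# scalar equation g = mean(gain * max(I - J_goc g - theta, 0)). (Plain
# fixed-point iteration diverges: the map's slope is about -gain*J_goc*f.)
solve_goc_mean <- function(I, gain, theta, J_goc) {
  h <- function(g) g - mean(gain * pmax(I - J_goc * g - theta, 0))
  hi <- mean(gain * pmax(I - theta, 0)) + 1
  stats::uniroot(h, c(0, hi), tol = 1e-12)$root
}

#' Steady-state GC rates under the Golgi loop
#'
#' Solves, per pattern, the implicit steady state
#' `gc_i = gain * max(I_i - J_goc * mean(gc) - theta, 0)`: the population
#' mean is the unique root of a monotone scalar equation, found by
#' bracketed root finding.
#'
#' @param model A `circuit_model` with `J_goc` set (see
#'   [golgi_self_consistent()]).
#' @param patterns `n_mf x P` rate matrix.
#' @return `n_gc x P` matrix of steady-state GC rates.
#' @export
golgi_steady_rates <- function(model, patterns) {
  if (is.null(model$J_goc)) stop("model has no Golgi weight", call. = FALSE)
  I <- gc_steady_inputs(model, patterns)
  out <- matrix(0, model$n_gc, ncol(I))
  for (p in seq_len(ncol(I))) {
    goc <- solve_goc_mean(I[, p], model$gain, model$threshold, model$J_goc)
    out[, p] <- model$gain * pmax(I[, p] - model$J_goc * goc -
                                    model$threshold, 0)
  }
  out
}
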