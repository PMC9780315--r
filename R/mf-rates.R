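# Mossy-fiber firing-rate ensembles. Rates are drawn per MF group either
# from a rectified ("thresholded") Gaussian whose UNDERLYING parameters are
# solved so the rectified distribution hits target moments, or from a
# uniform distribution.

rect_gauss_moments <- function(mu0, sigma0) {
  if (sigma0 <= 0) return(c(mean = max(mu0, 0), sd = 0))
  z <- mu0 / sigma0
  m1 <- mu0 * pnorm(z) + sigma0 * dnorm(z)
  m2 <- (mu0^2 + sigma0^2) * pnorm(z) + mu0 * sigma0 * dnorm(z)
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

#' Underlying Gaussian parameters for a target rectified distribution
#'
#' Finds `(mu0, sigma0)` such that `max(N(mu0, sigma0), 0)` has the requested
#' mean and standard deviation, by damped Newton iteration on the two moment
#' equations (residual tolerance 1e-8).
#'
#' @param mean,sd Target moments of the rectified distribution (Hz, `sd >= 0`).
#' @return Named vector `c(mu0, sigma0)`.
#' @export
rectified_gaussian_params <- function(mean, sd) {
  stopifnot_scalar(mean, "mean", lo = 0)
  stopifnot_scalar(sd, "sd", lo = 0)
  if (sd == 0) return(c(mu0 = mean, sigma0 = 0))
  if (mean == 0) stop("target mean 0 with positive sd is not attainable ",
                      "by a rectified Gaussian", call. = FALSE)
  f <- function(par) rect_gauss_moments(par[1], exp(par[2])) - c(mean, sd)
  par <- c(mean, log(sd))
  for (it in 1:200) {
    r <- f(par)
    if (max(abs(r)) < 1e-8 * max(1, mean)) break
    h <- 1e-6 * pmax(abs(par), 1)
    J <- cbind((f(par + c(h[1], 0)) - r) / h[1],
               (f(par + c(0, h[2])) - r) / h[2])
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) stop("moment equations are singular", call. = FALSE)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      if (max(abs(f(cand))) < max(abs(r)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    par <- par - lambda * step
  }
  if (max(abs(f(par))) >= 1e-8 * max(1, mean))
    stop(sprintf(paste0("could not match rectified-Gaussian moments ",
                        "(mean %.3g, sd %.3g): target sd too large ",
                        "relative to mean?"), mean, sd), call. = FALSE)
  c(mu0 = par[1], sigma0 = exp(par[2]))
}

#' Define the MF firing-rate ensemble
#'
#' One row per MF group. Thresholded-Gaussian groups (`dist = "tgauss"`) are
#' specified by the target mean/sd of the distribution AFTER negative values
#' are set to zero; the underlying Gaussian parameters are solved at
#' construction. Uniform groups are specified by bounds. `zero_fraction`
#' forces that fraction of a group's fibers to rate 0 in every pattern.
#'
#' @param group_id Character labels matching a synapse registry.
#' @param dist `"tgauss"` or `"uniform"` per group.
#' @param mean,sd Target moments for tgauss groups (Hz; `NA` for uniform).
#' @param lo,hi Bounds for uniform groups (Hz; `NA` for tgauss).
#' @param zero_fraction Fraction of fibers forced to 0 rate, in `[0, 1]`.
#' @param occurrence Relative frequency of each group (sums to 1).
#' @return Data frame of class `mf_rate_spec` with solved `mu0`, `sigma0`
#'   columns for tgauss rows.
#' @export
mf_rate_spec <- function(group_id, dist, mean = NA, sd = NA, lo = NA, hi = NA,
                         zero_fraction = 0, occurrence) {
  n <- length(group_id)
  spec <- data.frame(group_id = as.character(group_id),
                     dist = rep_len(dist, n),
                     mean = rep_len(as.numeric(mean), n),
                     sd = rep_len(as.numeric(sd), n),
                     lo = rep_len(as.numeric(lo), n),
                     hi = rep_len(as.numeric(hi), n),
                     zero_fraction = rep_len(zero_fraction, n),
                     occurrence = rep_len(occurrence, n),
                     mu0 = NA_real_, sigma0 = NA_real_,
                     stringsAsFactors = FALSE)
  if (abs(sum(spec$occurrence) - 1) > 1e-9)
    stop("group occurrences must sum to 1", call. = FALSE)
  for (i in seq_len(n)) {
    if (spec$dist[i] == "tgauss") {
      p <- rectified_gaussian_params(spec$mean[i], spec$sd[i])
      spec$mu0[i] <- p[["mu0"]]; spec$sigma0[i] <- p[["sigma0"]]
    } else if (spec$dist[i] != "uniform") {
      stop("dist must be 'tgauss' or 'uniform'", call. = FALSE)
    }
  }
  class(spec) <- c("mf_rate_spec", "data.frame")
  spec
}

#' Built-in MF rate ensembles
#'
#' `"table2"`: the full-model ensemble -- thresholded Gaussians with target
#' mean 200 Hz (groups 1, 2) or 20 Hz (groups 3-5) and target sd 20 Hz,
#' occurrences matching the full synapse registry. `"reduced-reference"`:
#' driver/supporter thresholded Gaussians (200, 15) and (25, 15) Hz used with
#' the reduced registry. `"reduced-bayes"`: the reduced-model interval-timing
#' variant, (200, 10) and (20, 15) Hz.
#'
#' @param name Ensemble name.
#' @return An `mf_rate_spec`.
#' @export
builtin_rate_spec <- function(name = c("table2", "reduced-reference",
                                       "reduced-bayes")) {
  name <- match.arg(name)
  switch(name,
    "table2" = mf_rate_spec(
      group_id = as.character(1:5), dist = "tgauss",
      mean = c(200, 200, 20, 20, 20), sd = 20,
      occurrence = c(0.06, 0.16, 0.38, 0.24, 0.16)),
    "reduced-reference" = mf_rate_spec(
      group_id = c("driver", "supporter"), dist = "tgauss",
      mean = c(200, 25), sd = c(15, 15), occurrence = c(0.5, 0.5)),
    "reduced-bayes" = mf_rate_spec(
      group_id = c("driver", "supporter"), dist = "tgauss",
      mean = c(200, 20), sd = c(10, 15), occurrence = c(0.5, 0.5)))
}

#' Split a uniform rate range into contiguous equal groups
#'
#' Splits `uniform(lo, hi)` into `n_groups` contiguous sub-ranges of equal
#' width and returns their bounds and standard deviations
#' (`width / (n_groups * sqrt(12))` each).
#'
#' @param lo,hi Bounds of the parent uniform distribution (Hz).
#' @param n_groups Number of contiguous groups.
#' @param occurrence Optional occurrences (default equal).
#' @return An `mf_rate_spec` of uniform groups, ordered low to high.
#' @export
split_uniform_spec <- function(lo, hi, n_groups, occurrence = NULL) {
  edges <- seq(lo, hi, length.out = n_groups + 1)
  if (is.null(occurrence)) occurrence <- rep(1 / n_groups, n_groups)
  mf_rate_spec(group_id = as.character(seq_len(n_groups)), dist = "uniform",
               lo = edges[-length(edges)], hi = edges[-1],
               occurrence = occurrence)
}

#' Assign MF fibers to rate groups
#'
#' Deterministic largest-remainder apportionment of `n_mf` fibers to the
#' spec's groups in proportion to their occurrences.
#'
#' @param spec An `mf_rate_spec`.
#' @param n_mf Number of mossy fibers.
#' @return Integer vector of group indices (rows of `spec`), length `n_mf`.
#' @export
assign_mf_groups <- function(spec, n_mf) {
  quota <- spec$occurrence * n_mf
  base <- floor(quota)
  rem <- n_mf - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_len(nrow(spec)), times = base)
}

# Underlying (pre-rectification) draws: one column per pattern.
sample_mf_raw <- function(spec, mf_groups, n_patterns = 1L) {
  n_mf <- length(mf_groups)
  raw <- matrix(rnorm(n_mf * n_patterns), n_mf, n_patterns)
  mu0 <- ifelse(spec$dist[mf_groups] == "tgauss", spec$mu0[mf_groups], NA)
  s0 <- ifelse(spec$dist[mf_groups] == "tgauss", spec$sigma0[mf_groups], NA)
  raw * ifelse(is.na(s0), 1, s0) + ifelse(is.na(mu0), 0, mu0)
}

# Turn underlying draws into rates: rectify tgauss rows; map uniform rows
# through the normal CDF to their bounds (preserves the copula structure of
# `raw`). Applies per-group zero fractions.
rectify_mf_raw <- function(spec, mf_groups, raw) {
  raw <- as.matrix(raw)
  rates <- raw
  for (g in unique(mf_groups)) {
    idx <- which(mf_groups == g)
    if (spec$dist[g] == "tgauss") {
      rates[idx, ] <- pmax(raw[idx, , drop = FALSE], 0)
    } else {
      u <- pnorm((raw[idx, , drop = FALSE]))
      rates[idx, ] <- spec$lo[g] + u * (spec$hi[g] - spec$lo[g])
    }
    zf <- spec$zero_fraction[g]
    if (zf > 0) {
      nz <- round(zf * length(idx))
      if (nz > 0)
        for (p in seq_len(ncol(rates)))
          rates[idx[sample.int(length(idx), nz)], p] <- 0
    }
  }
  rates
}

#' Draw MF firing-rate patterns
#'
#' Each fiber's rate is drawn independently from its group's distribution.
#'
#' @param spec An `mf_rate_spec`.
#' @param mf_groups Group index per fiber (see [assign_mf_groups()]).
#' @param n_patterns Number of independent patterns.
#' @param seed Optional seed (the caller's RNG stream is untouched).
#' @return `length(mf_groups) x n_patterns` rate matrix (Hz).
#' @export
sample_mf_pattern <- function(spec, mf_groups, n_patterns = 1L, seed = NULL) {
  with_seed(seed, {
    raw <- sample_mf_raw(spec, mf_groups, n_patterns)
    rectify_mf_raw(spec, mf_groups, raw)
  })
}

#' Draw a sequence of correlated MF patterns
#'
#' Successive patterns share underlying Gaussian structure:
#' `raw_new = c * raw_old + sqrt(1 - c^2) * raw_fresh` (standardized scale),
#' then each pattern is rectified. `c = 0` gives independent re-draws, `c = 1`
#' repeats the same pattern.
#'
#' @inheritParams sample_mf_pattern
#' @param n_patterns Number of patterns in the chain.
#' @param c Correlation of successive underlying patterns, in `[0, 1]`.
#' @return Rate matrix, one column per pattern.
#' @export
sample_correlated_patterns <- function(spec, mf_groups, n_patterns, c,
                                       seed = NULL) {
  stopifnot_scalar(c, "c", lo = 0, hi = 1)
  with_seed(seed, {
    n_mf <- length(mf_groups)
    z <- matrix(NA_real_, n_mf, n_patterns)
    z[, 1] <- rnorm(n_mf)
    if (n_patterns > 1)
      for (p in 2:n_patterns)
        z[, p] <- c * z[, p - 1] + sqrt(1 - c^2) * rnorm(n_mf)
    mu0 <- ifelse(spec$dist[mf_groups] == "tgauss", spec$mu0[mf_groups], 0)
    s0 <- ifelse(spec$dist[mf_groups] == "tgauss", spec$sigma0[mf_groups], 1)
    rectify_mf_raw(spec, mf_groups, z * s0 + mu0)
  })
}

#' Sample release probabilities and rates with a target rank correlation
#'
#' Draws `n` synapses whose slow-pool release probability and MF firing rate
#' are each uniform on the given bounds, split into `n_groups` contiguous
#' categories, with a Gaussian copula inducing rank correlation `c_rk`
#' between the two. Marginals are preserved exactly: the drawn values are
#' only reordered against each other. Fast-pool release probabilities are
#' `(2/3) p_v_slow`, strictly lower.
#'
#' @param c_rk Target rank (Spearman) correlation in `[-1, 1]`.
#' @param pv_bounds,rate_bounds Bounds of the uniform marginals.
#' @param n_groups Number of contiguous categories (2 or 5).
#' @param n Number of synapses to draw.
#' @param seed Optional seed.
#' @return Data frame with `p_v_slow`, `p_v_fast`, `m`, `pv_group`,
#'   `rate_group`.
#' @export
sample_correlated_pv_rate <- function(c_rk, pv_bounds = c(0.1, 0.9),
                                      rate_bounds = c(5, 270),
                                      n_groups = 2, n = 1000, seed = NULL) {
  stopifnot_scalar(c_rk, "c_rk", lo = -1, hi = 1)
  with_seed(seed, {
    rho <- 2 * sin(pi * c_rk / 6)  # Pearson rho giving Spearman c_rk
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    pv <- runif(n, pv_bounds[1], pv_bounds[2])
    m <- runif(n, rate_bounds[1], rate_bounds[2])
    pv_sorted <- sort(pv)[rank(z1, ties.method = "first")]
    m_sorted <- sort(m)[rank(z2, ties.method = "first")]
    grp <- function(x, bounds) {
      edges <- seq(bounds[1], bounds[2], length.out = n_groups + 1)
      pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1), n_groups)
    }
    data.frame(p_v_slow = pv_sorted, p_v_fast = (2 / 3) * pv_sorted,
               m = m_sorted,
               pv_group = grp(pv_sorted, pv_bounds),
               rate_group = grp(m_sorted, rate_bounds))
  })
}
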