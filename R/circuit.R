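# Circuit assembly: mossy fibers (MF) -> granule cells (GC) -> one Purkinje
# cell (PC), with a molecular-layer interneuron (MLI) carrying the GC
# population mean as feed-forward inhibition. Each GC receives exactly four
# MF synapses; the synapse type is the type of the presynaptic fiber.

#' Wire granule cells to mossy fibers
#'
#' In `"full"` mode each GC draws 4 distinct fibers uniformly; draws in which
#' no input fiber belongs to one of `required_groups` are rejected and
#' redrawn (the biological constraint that every GC receives at least one
#' primary-sensory-type input). In `"reduced"` mode each GC receives exactly
#' two driver and two supporter fibers, all distinct.
#'
#' @param n_mf Number of mossy fibers (`>= 4`).
#' @param n_gc Number of granule cells.
#' @param mf_groups Group index per fiber (rows of the registry).
#' @param registry The `synapse_registry` (for group labels).
#' @param mode `"full"` or `"reduced"`.
#' @param required_groups Character group ids of which every GC needs at
#'   least one input fiber (full mode; `NULL` disables the constraint).
#' @param seed Optional seed.
#' @return Integer matrix `n_gc x 4` of fiber indices.
#' @export
build_connectivity <- function(n_mf, n_gc, mf_groups, registry,
                               mode = c("full", "reduced"),
                               required_groups = c("1", "2", "5"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (n_mf < 4) stop("need at least 4 mossy fibers", call. = FALSE)
  with_seed(seed, {
    if (mode == "reduced") {
      drv <- which(registry$group_id[mf_groups] == "driver")
      sup <- which(registry$group_id[mf_groups] == "supporter")
      if (length(drv) < 2 || length(sup) < 2)
        stop("reduced mode needs >= 2 driver and >= 2 supporter fibers",
             call. = FALSE)
      conn <- t(vapply(seq_len(n_gc), function(i)
        c(drv[sample.int(length(drv), 2)], sup[sample.int(length(sup), 2)]),
        integer(4)))
    } else {
      req <- !is.null(required_groups) &&
        any(registry$group_id[mf_groups] %in% required_groups)
      if (!is.null(required_groups) && !req)
        stop("no fiber belongs to the required groups; constraint infeasible",
             call. = FALSE)
      in_req <- registry$group_id[mf_groups] %in% required_groups
      draw <- function(k) t(vapply(seq_len(k), function(i)
        sample.int(n_mf, 4), integer(4)))
      conn <- draw(n_gc)
      if (req) {
        repeat {
          bad <- which(rowSums(matrix(in_req[conn], nrow(conn))) == 0)
          if (!length(bad)) break
          conn[bad, ] <- draw(length(bad))
        }
      }
    }
    conn
  })
}

#' Assemble a cerebellar circuit model
#'
#' Binds together the synapse registry, the MF rate ensemble, the wiring, the
#' (uncalibrated) GC gains and thresholds, and the readout weights. Spec of
#' the readout: `I_pc = (1/N) sum_i (J_E_i - J_I) gc_i + I_spont`,
#' `pc = max(I_pc, 0)`; `mli` is the GC population mean. The spontaneous
#' drive `I_spont` keeps the PC at its 40 Hz baseline when excitation and
#' inhibition cancel (`J_E = J_I`), which is also the initial condition for
#' learning.
#'
#' @param registry A `synapse_registry`.
#' @param rate_spec An `mf_rate_spec` with the same group ids (row order must
#'   match).
#' @param n_mf,n_gc Layer sizes.
#' @param mode `"full"` (GC membrane time constant `tau_g`) or `"reduced"`
#'   (instantaneous GCs).
#' @param tau_g GC membrane time constant (s), full mode.
#' @param J_I MLI-to-PC weight; `J_E` is initialized to the same value.
#' @param I_spont PC baseline drive (rate units, 40 Hz).
#' @param required_groups Passed to [build_connectivity()] in full mode.
#' @param seed Optional seed for the wiring.
#' @return A list of class `circuit_model`.
#' @export
circuit_model <- function(registry, rate_spec, n_mf = 100, n_gc = 3000,
                          mode = c("full", "reduced"), tau_g = 0.010,
                          J_I = 10, I_spont = 40,
                          required_groups = c("1", "2", "5"), seed = NULL) {
  mode <- match.arg(mode)
  if (!identical(registry$group_id, rate_spec$group_id))
    stop("registry and rate spec group ids must match", call. = FALSE)
  mf_groups <- assign_mf_groups(rate_spec, n_mf)
  conn <- build_connectivity(n_mf, n_gc, mf_groups, registry, mode,
                             required_groups = if (mode == "full")
                               required_groups else NULL,
                             seed = seed)
  C <- Matrix::sparseMatrix(i = rep(seq_len(n_gc), 4), j = as.vector(conn),
                            x = 1, dims = c(n_gc, n_mf))
  structure(list(registry = registry, rate_spec = rate_spec,
                 n_mf = n_mf, n_gc = n_gc, mode = mode,
                 mf_groups = mf_groups, conn = conn, C = C,
                 tau_g = tau_g, J_E = rep(J_I, n_gc), J_I = J_I,
                 I_spont = I_spont, gain = rep(NA_real_, n_gc),
                 threshold = rep(NA_real_, n_gc), J_goc = NULL),
            class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("<circuit_model: %s mode, %d MFs, %d GCs, %s>\n", x$mode,
              x$n_mf, x$n_gc,
              if (all(is.na(x$gain))) "uncalibrated" else "calibrated"))
  invisible(x)
}

# Steady-state synaptic drive to every GC for a batch of MF patterns.
# patterns: n_mf x P rate matrix; returns n_gc x P.
gc_steady_inputs <- function(model, patterns) {
  patterns <- as.matrix(patterns)
  P <- ncol(patterns)
  idx <- rep(model$mf_groups, P)
  st <- stp_steady_state(model$registry[idx, ], as.vector(patterns),
                         model = model$mode)
  W <- matrix(synaptic_weight(st, model$registry[idx, ]), model$n_mf, P)
  as.matrix(model$C %*% (W * patterns))
}

#' Calibrate granule-cell gains and thresholds
#'
#' Sets each GC's threshold to the `1 - sparsity` quantile of its
#' steady-state input distribution over `n_patterns` random MF patterns (so
#' the GC is active on a fraction `sparsity` of patterns) and its gain so
#' that its mean steady-state rate over patterns equals `target_rate`. A GC
#' with a degenerate (all-equal) input distribution is flagged and its gain
#' set to 0.
#'
#' @param model A `circuit_model`.
#' @param n_patterns Number of calibration patterns (1000).
#' @param target_rate Mean steady-state GC rate target (Hz, 5).
#' @param sparsity Lifetime sparsity target (0.2).
#' @param seed Optional seed for the calibration patterns.
#' @return The model with `gain`, `threshold` and a `calibration` record
#'   filled in.
#' @export
calibrate_gc <- function(model, n_patterns = 1000, target_rate = 5,
                         sparsity = 0.2, seed = NULL) {
  patterns <- sample_mf_pattern(model$rate_spec, model$mf_groups,
                                n_patterns, seed = seed)
  I <- gc_steady_inputs(model, patterns)
  theta <- apply(I, 1, stats::quantile, probs = 1 - sparsity, names = FALSE)
  active <- pmax(I - theta, 0)
  mean_active <- rowMeans(active)
  degenerate <- apply(I, 1, function(r) diff(range(r)) < 1e-12) |
    mean_active <= 0
  gain <- ifelse(degenerate, 0, target_rate / mean_active)
  model$gain <- gain
  model$threshold <- theta
  model$calibration <- list(n_patterns = n_patterns,
                            target_rate = target_rate, sparsity = sparsity,
                            degenerate = which(degenerate))
  model
}

#' Steady-state GC rates for a batch of patterns
#'
#' `gc* = gain * max(I* - threshold, 0)` per GC and pattern; requires a
#' calibrated model.
#'
#' @inheritParams calibrate_gc
#' @param patterns `n_mf x P` rate matrix.
#' @return `n_gc x P` rate matrix (Hz).
#' @export
gc_steady_rates <- function(model, patterns) {
  if (all(is.na(model$gain))) stop("model is not calibrated", call. = FALSE)
  I <- gc_steady_inputs(model, patterns)
  model$gain * pmax(I - model$threshold, 0)
}

#' Build a piecewise-constant MF rate schedule
#'
#' @param rates `n_mf x n_segments` rate matrix, one column per segment.
#' @param durations Segment durations (s), recycled.
#' @return A list of class `mf_schedule`.
#' @export
mf_schedule <- function(rates, durations) {
  rates <- as.matrix(rates)
  durations <- rep_len(durations, ncol(rates))
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  structure(list(rates = rates, durations = durations), class = "mf_schedule")
}

#' Simulate the circuit under a piecewise-constant MF schedule
#'
#' Explicit Euler integration at step `dt` (0.5 ms by default). Synapse
#' states are initialized at the analytic steady state under the first
#' segment's rates (the pre-stimulus window is assumed stationary) and GC
#' rates at their corresponding steady-state values. At every step:
#' synaptic weights evolve per the STP equations, `I_gc = C (W * m)`,
#' full-mode GCs low-pass the rectified drive with `tau_g` while reduced-mode
#' GCs follow it instantaneously, `mli` is the GC mean, and
#' `pc = max((1/N) sum (J_E - J_I) gc + I_spont, 0)`.
#'
#' With `stp_off = TRUE` all synapse states stay frozen at their initial
#' steady state, so rate switches reach the GCs only through the (static)
#' initial weights -- the control in which the temporal basis is removed.
#'
#' GC traces are recorded as averages over consecutive blocks of
#' `gc_stride` steps (5 ms blocks by default), the same quadrature the
#' learning rule uses; PC and MLI are recorded at every step.
#'
#' @param model A calibrated `circuit_model`.
#' @param schedule An [mf_schedule()]; segment durations must be integer
#'   multiples of `dt`.
#' @param dt Euler step (s).
#' @param stp_off Freeze synapse dynamics (control condition).
#' @param record_gc Record block-averaged GC traces.
#' @param gc_stride Steps per GC recording block.
#' @param goc_lag With a Golgi loop (`model$J_goc` set), the GC mean feeding
#'   back is taken from the previous step.
#' @return A list of class `trial_trace`: `time` (step grid, s), `pc`, `mli`
#'   (Hz), `gc` (`n_blocks x n_gc` block means) with `gc_time` (block
#'   centers), `mf` (`n_steps x n_mf` applied rates), `dt`.
#' @export
simulate_circuit <- function(model, schedule, dt = 5e-4, stp_off = FALSE,
                             record_gc = TRUE, gc_stride = 10L,
                             goc_lag = TRUE) {
  if (all(is.na(model$gain))) stop("model is not calibrated", call. = FALSE)
  stopifnot(inherits(schedule, "mf_schedule"))
  n_steps_seg <- schedule$durations / dt
  if (any(abs(n_steps_seg - round(n_steps_seg)) > 1e-6))
    stop("segment durations must be integer multiples of dt", call. = FALSE)
  n_steps_seg <- as.integer(round(n_steps_seg))
  n_steps <- sum(n_steps_seg)
  seg_of_step <- rep(seq_along(n_steps_seg), n_steps_seg)

  reg <- model$registry[model$mf_groups, ]
  full <- model$mode == "full"
  # plain vectors for the inner loop
  Ns <- reg$N_slow; Nf <- reg$N_fast
  pvs <- reg$p_v_slow; pvf <- reg$p_v_fast
  trs <- reg$tau_ref_slow; trf <- reg$tau_ref_fast
  tf <- ifelse(is.na(reg$tau_F), Inf, reg$tau_F)
  pref <- reg$p_ref; q0 <- reg$q0
  dd <- ifelse(is.na(reg$Delta_D), 0, reg$Delta_D)
  td <- ifelse(is.na(reg$tau_D), Inf, reg$tau_D)
  has_slow <- Ns > 0
  ntot <- Ns + Nf

  m0 <- schedule$rates[, 1]
  st <- stp_steady_state(reg, m0, model = model$mode)
  xs <- ifelse(has_slow, st$x_slow, 0)
  xf <- st$x_fast
  us <- ifelse(has_slow, st$u_slow, 0)
  uf <- st$u_fast
  q <- st$q
  pvs0 <- ifelse(has_slow, pvs, 0)
  W0 <- q * (Ns * us * xs + Nf * uf * xf)

  gain <- model$gain; theta <- model$threshold
  dJ <- (model$J_E - model$J_I) / model$n_gc
  J_goc <- if (is.null(model$J_goc)) 0 else model$J_goc
  I0 <- as.vector(model$C %*% (W0 * m0))
  goc <- if (J_goc > 0) solve_goc_mean(I0, gain, theta, J_goc) else 0
  gc <- gain * pmax(I0 - J_goc * goc - theta, 0)

  pc_tr <- numeric(n_steps); mli_tr <- numeric(n_steps)
  n_blocks <- n_steps %/% gc_stride
  gc_tr <- if (record_gc) matrix(0, n_blocks, model$n_gc) else NULL
  gc_acc <- numeric(model$n_gc); blk <- 0L
  mf_tr <- matrix(0, n_steps, model$n_mf)

  for (k in seq_len(n_steps)) {
    m <- schedule$rates[, seg_of_step[k]]
    mf_tr[k, ] <- m
    if (!stp_off) {
      if (full) {
        us_new <- us + dt * ((pvs0 - us) / tf + pvs0 * (1 - us) * m)
        uf_new <- uf + dt * ((pvf - uf) / tf + pvf * (1 - uf) * m)
        rel <- Ns * us * xs + Nf * uf * xf
        q <- pmin(pmax(q + dt * ((q0 - q) / td - dd * q * rel / ntot * m),
                       0), q0)
      }
      xs <- xs + dt * ((1 - xs) / trs - us * (1 - pref) * xs * m)
      xs[!has_slow] <- 0
      xf <- xf + dt * ((1 - xf) / trf - uf * xf * m)
      xs <- pmin(pmax(xs, 0), 1); xf <- pmin(pmax(xf, 0), 1)
      if (full) {
        us <- pmin(pmax(us_new, 0), 1); uf <- pmin(pmax(uf_new, 0), 1)
      }
      W <- q * (Ns * us * xs + Nf * uf * xf)
    } else {
      W <- W0
    }
    I_gc <- as.vector(model$C %*% (W * m))
    if (J_goc > 0) {
      # full mode: GoC follows last step's GC mean (stable through tau_g);
      # reduced mode (instantaneous GCs): solve the loop implicitly
      goc <- if (full && goc_lag) mean(gc)
             else solve_goc_mean(I_gc, gain, theta, J_goc)
    }
    drive <- gain * pmax(I_gc - J_goc * goc - theta, 0)
    gc <- if (full) gc + (dt / model$tau_g) * (drive - gc) else drive
    mli_tr[k] <- mean(gc)
    pc_tr[k] <- max(sum(dJ * gc) + model$I_spont, 0)
    if (record_gc) {
      gc_acc <- gc_acc + gc
      if (k %% gc_stride == 0L) {
        blk <- blk + 1L
        gc_tr[blk, ] <- gc_acc / gc_stride
        gc_acc[] <- 0
      }
    }
  }
  structure(list(time = seq_len(n_steps) * dt, dt = dt,
                 pc = pc_tr, mli = mli_tr, gc = gc_tr,
                 gc_time = if (record_gc)
                   (seq_len(n_blocks) - 0.5) * gc_stride * dt else NULL,
                 mf = mf_tr, stp_off = stp_off),
            class = "trial_trace")
}
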