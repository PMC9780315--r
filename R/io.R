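# Configuration files, result serialization, and seeded miniature fixtures.

run_config_schema <- list(
  model = c("mode", "registry", "rate_spec", "n_mf", "n_gc", "tau_g",
            "J_I", "I_spont", "seed"),
  experiment = c("task", "delays", "priors", "n_switches", "period", "c",
                 "realizations", "t_target", "J_pc"),
  learning = c("eta", "beta", "cf_spont", "T_pre", "T_CS", "w_err_peak",
               "subsample_factor", "n_trials", "J_init", "I_spont", "dt",
               "snapshot_every", "seed"),
  output = c("dir"))

#' Read a run configuration (JSON or YAML)
#'
#' Configurations have sections `model`, `experiment`, `learning`, `output`.
#' Unknown sections or keys are rejected before any computation.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  bad_sec <- setdiff(names(cfg), names(run_config_schema))
  if (length(bad_sec))
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), run_config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in [%s]: %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(cfg$model$rate_spec) && is.character(cfg$model$rate_spec)) {
    spec <- builtin_rate_spec(cfg$model$rate_spec)
    if (abs(sum(spec$occurrence) - 1) > 1e-9)
      stop("rate-spec group occurrences must sum to 1", call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Write a (fully resolved) run configuration as JSON
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a trial trace to long-format CSV
#'
#' Columns `time`, `unit_type` (`mf`, `gc`, `mli`, `pc`), `unit_id`, `rate`.
#' GC rows are on the block-averaged grid; MF, MLI and PC rows on the Euler
#' grid.
#'
#' @param trace A `trial_trace`.
#' @param path Output path.
#' @param include_mf Write the (large) per-step MF rates too.
#' @export
trace_to_csv <- function(trace, path, include_mf = FALSE) {
  rows <- list(
    data.frame(time = trace$time, unit_type = "pc", unit_id = 1L,
               rate = trace$pc),
    data.frame(time = trace$time, unit_type = "mli", unit_id = 1L,
               rate = trace$mli))
  if (!is.null(trace$gc)) {
    n_gc <- ncol(trace$gc)
    rows[[length(rows) + 1]] <-
      data.frame(time = rep(trace$gc_time, n_gc),
                 unit_type = "gc",
                 unit_id = rep(seq_len(n_gc), each = length(trace$gc_time)),
                 rate = as.vector(trace$gc))
  }
  if (include_mf && !is.null(trace$mf)) {
    n_mf <- ncol(trace$mf)
    rows[[length(rows) + 1]] <-
      data.frame(time = rep(trace$time, n_mf),
                 unit_type = "mf",
                 unit_id = rep(seq_len(n_mf), each = length(trace$time)),
                 rate = as.vector(trace$mf))
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace_to_csv
#' @return `trace_from_csv` returns the long-format data frame.
#' @export
trace_from_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a learning result (loss curve, weights, config)
#'
#' Writes `loss.csv`, `weights.csv` and `config.json` into `dir`.
#'
#' @param result A `learning_result`.
#' @param dir Output directory (created if needed).
#' @export
export_learning_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(trial = seq_along(result$loss),
                              loss = result$loss),
                   file.path(dir, "loss.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gc = seq_along(result$J_E), J_E = result$J_E),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  cfg <- result$config
  cfg$seed <- if (is.null(cfg$seed)) NA else cfg$seed
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Deterministic miniature inputs for tests and examples
#'
#' * `"tiny-circuit"`: calibrated full model with 20 MFs and 100 GCs.
#' * `"step-protocol"`: the tiny circuit plus a pre/stimulus pattern pair.
#' * `"synthetic-pause"`: a Gaussian-dip PC trace (40 Hz baseline, 20 Hz
#'   depth, sd 30 ms, centered at 250 ms) with its time grid -- closed-form
#'   geometry for the pause metrics.
#' * `"bls-curves"`: noiseless BLS estimator curves with a planted Weber
#'   fraction of 0.15 over the five standard priors.
#'
#' @param kind Fixture name.
#' @param seed Seed.
#' @return A list; content depends on `kind`.
#' @export
make_fixture <- function(kind = c("tiny-circuit", "step-protocol",
                                  "synthetic-pause", "bls-curves"),
                         seed = 1) {
  kind <- match.arg(kind)
  if (kind == "tiny-circuit" || kind == "step-protocol") {
    model <- circuit_model(builtin_registry("table1"),
                           builtin_rate_spec("table2"),
                           n_mf = 20, n_gc = 100,
                           seed = child_seed(seed, 1))
    model <- calibrate_gc(model, n_patterns = 200,
                          seed = child_seed(seed, 2))
    if (kind == "tiny-circuit") return(list(model = model))
    pats <- sample_mf_pattern(model$rate_spec, model$mf_groups, 2,
                              seed = child_seed(seed, 3))
    return(list(model = model, m_pre = pats[, 1], m_cs = pats[, 2]))
  }
  if (kind == "synthetic-pause") {
    time <- seq(-0.1, 1.4, by = 5e-3)
    pc <- 40 - 20 * exp(-(time - 0.25)^2 / (2 * 0.03^2))
    return(list(time = time, pc = pc, baseline = 40, depth = 20,
                sigma = 0.03, center = 0.25))
  }
  priors <- list(c(0.025, 0.150), c(0.050, 0.200), c(0.100, 0.300),
                 c(0.200, 0.400), c(0.300, 0.500))
  w <- 0.15
  curves <- lapply(priors, function(pr) {
    t_m <- seq(pr[1], pr[2], length.out = 60)
    data.frame(t_m = t_m, t_e = bls_estimate(t_m, pr, w))
  })
  list(curves = curves, priors = priors, w_planted = w)
}
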