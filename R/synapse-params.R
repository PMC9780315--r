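#' Define one mossy-fiber to granule-cell synapse type
#'
#' A synapse type ("group") collects the quantal and kinetic constants of the
#' two-pool vesicle model: release-site counts and release probabilities for a
#' slow-refilling and a fast-refilling readily releasable pool, pool refill
#' time constants, the facilitation time constant, the immediate-refill
#' probability of the slow pool, and the desensitization parameters acting on
#' the normalized quantal size.
#'
#' Release-site counts may be fractional (the model is mean-field; `N` is a
#' scale factor). A group may lack the slow pool entirely (`N_slow = 0`), in
#' which case the slow-pool kinetic fields are ignored.
#'
#' @param group_id Character label for the group.
#' @param N_slow,N_fast Release-site counts (dimensionless, `>= 0`).
#' @param p_v_slow,p_v_fast Vesicle fusion probabilities in `[0, 1]`
#'   (`p_v_slow` ignored when `N_slow = 0`).
#' @param tau_ref_slow,tau_ref_fast Pool refill time constants (s).
#' @param tau_F Facilitation time constant (s), or `NA` for a model without
#'   facilitation (release probabilities then stay at `p_v`).
#' @param p_ref Probability of immediately refilling a slow-pool docking site
#'   after release, in `[0, 1]`.
#' @param Delta_D Desensitization proportionality factor (dimensionless); `NA`
#'   disables desensitization.
#' @param tau_D Desensitization recovery time constant (s).
#' @param q0 Quantal size in the absence of stimulation (normalized, 1).
#' @param occurrence Relative frequency of the group in `[0, 1]`.
#' @return A one-row data frame of class `synapse_group`.
#' @seealso [synapse_registry()], [builtin_registry()]
#' @export
synapse_group <- function(group_id, N_slow, N_fast, p_v_slow, p_v_fast,
                          tau_ref_slow = 2, tau_ref_fast = 0.02,
                          tau_F = NA_real_, p_ref = 0.6,
                          Delta_D = NA_real_, tau_D = NA_real_,
                          q0 = 1, occurrence = 1) {
  stopifnot_scalar(N_slow, "N_slow", lo = 0)
  stopifnot_scalar(N_fast, "N_fast", lo = 0)
  stopifnot_scalar(p_v_fast, "p_v_fast", lo = 0, hi = 1)
  stopifnot_scalar(occurrence, "occurrence", lo = 0, hi = 1)
  stopifnot_scalar(tau_ref_fast, "tau_ref_fast", lo = 1e-12)
  if (N_slow > 0) {
    stopifnot_scalar(p_v_slow, "p_v_slow", lo = 0, hi = 1)
    stopifnot_scalar(tau_ref_slow, "tau_ref_slow", lo = 1e-12)
    stopifnot_scalar(p_ref, "p_ref", lo = 0, hi = 1)
  } else {
    p_v_slow <- NA_real_; tau_ref_slow <- NA_real_; p_ref <- NA_real_
  }
  if (!is.na(tau_F)) stopifnot_scalar(tau_F, "tau_F", lo = 1e-12)
  if (!is.na(Delta_D)) {
    stopifnot_scalar(Delta_D, "Delta_D", lo = 0)
    stopifnot_scalar(tau_D, "tau_D", lo = 1e-12)
  }
  out <- data.frame(group_id = as.character(group_id),
                    N_slow = N_slow, N_fast = N_fast,
                    p_v_slow = p_v_slow, p_v_fast = p_v_fast,
                    tau_ref_slow = tau_ref_slow, tau_ref_fast = tau_ref_fast,
                    tau_F = tau_F, p_ref = p_ref,
                    Delta_D = Delta_D, tau_D = tau_D,
                    q0 = q0, occurrence = occurrence,
                    stringsAsFactors = FALSE)
  class(out) <- c("synapse_group", class(out))
  out
}

#' Collect synapse types into a registry
#'
#' A registry is the parameter table for one model variant: one row per
#' synapse type, occurrences summing to 1.
#'
#' @param ... `synapse_group` rows (or a single list of them).
#' @return A data frame of class `synapse_registry`.
#' @export
synapse_registry <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && !inherits(groups[[1]], "synapse_group"))
    groups <- groups[[1]]
  reg <- do.call(rbind, lapply(groups, as.data.frame))
  if (anyDuplicated(reg$group_id))
    stop("duplicate group_id in registry", call. = FALSE)
  if (abs(sum(reg$occurrence) - 1) > 1e-9)
    stop("group occurrences must sum to 1", call. = FALSE)
  rownames(reg) <- NULL
  class(reg) <- c("synapse_registry", "data.frame")
  reg
}

#' Built-in synapse parameter registries
#'
#' `"table1"` (alias `"full"`) holds the five experimentally constrained
#' synapse types of the full model, including facilitation and
#' desensitization; group 4 has no slow pool. `"table3"` (alias `"reduced"`)
#' holds the two-type driver/supporter registry of the reduced model, which
#' has constant release probabilities and no desensitization.
#'
#' The facilitation constant is 12 ms for groups 1-4 and 30 ms for group 5:
#' group 5 is the one facilitation-dominated type (paired-pulse ratio above
#' one), which is why it alone gets the longer constant (see the methods
#' vignette for the reasoning).
#'
#' @param name `"table1"`, `"full"`, `"table3"`, or `"reduced"`.
#' @return A `synapse_registry`.
#' @export
builtin_registry <- function(name = c("table1", "full", "table3", "reduced")) {
  name <- match.arg(name)
  if (name %in% c("table1", "full")) {
    synapse_registry(
      synapse_group("1", N_slow = 4, N_fast = 16, p_v_slow = 0.9,
                    p_v_fast = 0.72, tau_F = 0.012, Delta_D = 0.1,
                    tau_D = 0.1, occurrence = 0.06),
      synapse_group("2", N_slow = 3, N_fast = 12, p_v_slow = 0.8,
                    p_v_fast = 0.55, tau_F = 0.012, Delta_D = 0.1,
                    tau_D = 0.1, occurrence = 0.16),
      synapse_group("3", N_slow = 4, N_fast = 6, p_v_slow = 0.4,
                    p_v_fast = 0.35, tau_F = 0.012, Delta_D = 0.1,
                    tau_D = 0.1, occurrence = 0.38),
      synapse_group("4", N_slow = 0, N_fast = 10, p_v_slow = NA,
                    p_v_fast = 0.3, tau_F = 0.012, Delta_D = 0.1,
                    tau_D = 0.1, occurrence = 0.24),
      synapse_group("5", N_slow = 3, N_fast = 12, p_v_slow = 0.4,
                    p_v_fast = 0.15, tau_F = 0.03, Delta_D = 0.1,
                    tau_D = 0.1, occurrence = 0.16))
  } else {
    synapse_registry(
      synapse_group("driver", N_slow = 3.5, N_fast = 14, p_v_slow = 0.8,
                    p_v_fast = 0.6, occurrence = 0.5),
      synapse_group("supporter", N_slow = 4, N_fast = 6, p_v_slow = 0.4,
                    p_v_fast = 0.2, occurrence = 0.5))
  }
}

#' Serialize / restore a synapse registry as JSON
#'
#' Round trip is bit-exact: numeric fields are written at full precision and
#' restored unchanged.
#'
#' @param registry A `synapse_registry`.
#' @param path File path; for `registry_to_json` with `path = NULL` the JSON
#'   string is returned instead.
#' @return `registry_from_json` returns a `synapse_registry`.
#' @export
registry_to_json <- function(registry, path = NULL) {
  txt <- jsonlite::toJSON(as.data.frame(registry), digits = NA, na = "null",
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname registry_to_json
#' @export
registry_from_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  num <- setdiff(names(df), "group_id")
  df[num] <- lapply(df[num], function(x) {
    x <- as.numeric(x); x[is.null(x)] <- NA_real_; x
  })
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    synapse_group(r$group_id, r$N_slow, r$N_fast, r$p_v_slow, r$p_v_fast,
                  r$tau_ref_slow, r$tau_ref_fast, r$tau_F, r$p_ref,
                  r$Delta_D, r$tau_D, r$q0, r$occurrence)
  })
  synapse_registry(rows)
}
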