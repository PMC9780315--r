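# Shared, lazily built model fixtures. Building a calibrated circuit takes a
# couple of seconds, so tests share instances through this cache.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

tiny_full_model <- function() cached("tiny_full", function() {
  m <- circuit_model(builtin_registry("table1"), builtin_rate_spec("table2"),
                     n_mf = 40, n_gc = 120, seed = 101)
  calibrate_gc(m, n_patterns = 300, seed = 102)
})

small_full_model <- function() cached("small_full", function() {
  m <- circuit_model(builtin_registry("table1"), builtin_rate_spec("table2"),
                     n_mf = 100, n_gc = 300, seed = 21)
  calibrate_gc(m, n_patterns = 1000, seed = 22)
})

small_reduced_model <- function() cached("small_reduced", function() {
  m <- circuit_model(builtin_registry("table3"),
                     builtin_rate_spec("reduced-reference"),
                     n_mf = 100, n_gc = 400, mode = "reduced", seed = 31)
  calibrate_gc(m, n_patterns = 800, seed = 32)
})

# learning-window GC basis of the small full model, shared across tests
small_basis <- function(cfg = learning_config(n_trials = 1000)) {
  cached("small_basis", function() {
    m <- small_full_model()
    pats <- sample_mf_pattern(m$rate_spec, m$mf_groups, 2, seed = 23)
    gc_basis(m, pats[, 1], pats[, 2], cfg)
  })
}
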