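# memoised condition runs shared across test files (everything is
# deterministic, so caching cannot change any result)
.sim_cache <- new.env(parent = emptyenv())

all_builtin_configs <- function() {
  c(builtin_sequences(), builtin_predictions())
}

cached_result <- function(name) {
  key <- paste0("res_", name)
  if (!exists(key, envir = .sim_cache)) {
    cfg <- all_builtin_configs()[[name]]
    stopifnot(!is.null(cfg))
    assign(key, run_model(cfg), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_report <- function(name) {
  key <- paste0("rep_", name)
  if (!exists(key, envir = .sim_cache)) {
    cfg <- all_builtin_configs()[[name]]
    assign(key, run_sequence(cfg, result = cached_result(name)),
           envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

seq_names <- function() names(builtin_sequences())
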