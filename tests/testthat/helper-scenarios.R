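# scenario runs are expensive; memoise them so several test blocks can share
# one set of replicates
.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(id, reps, seed) {
  key <- paste(id, reps, seed, sep = "|")
  if (is.null(.scenario_cache[[key]]))
    .scenario_cache[[key]] <- run_scenario(id, reps, scenario_config(),
                                           seed = seed)
  .scenario_cache[[key]]
}

scenario_mean <- function(res, approach, metric, strategy) {
  v <- res$results
  mean(v$value[v$approach == approach & v$metric == metric &
                 v$strategy == strategy], na.rm = TRUE)
}

scenario_values <- function(res, approach, metric, strategy) {
  v <- res$results
  v$value[v$approach == approach & v$metric == metric & v$strategy == strategy]
}
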