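# Shared fixtures, built once per test run and memoised: the default seeded
# simulation, its condition summaries, and MLP surrogates trained on them.

.fixtures <- new.env(parent = emptyenv())

default_records <- function() {
  if (is.null(.fixtures$records)) {
    .fixtures$records <- simulate_experiment(generator_config(seed = 1))
  }
  .fixtures$records
}

default_summaries <- function() {
  if (is.null(.fixtures$summaries)) {
    .fixtures$summaries <- condition_summaries(default_records(),
                                               speed_mode = "inverted")
  }
  .fixtures$summaries
}

default_mlp <- function(target) {
  key <- paste0("mlp_", target)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- train_mlp(default_summaries(), target,
                                  mlp_config(seed = 1))
  }
  .fixtures[[key]]
}

condition_key <- function(d) {
  paste(d$treatment_id, d$explant, d$ms_level, d$sampling_day)
}
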