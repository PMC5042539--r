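# Shared fixtures: the default model and its equilibrated baseline are
# computed once per test run.

fix_default <- default_fixture()
model_default <- build_ketone_model(fix_default)
baseline_default <- equilibrate(model_default)

nonsink_ids <- function(model) {
  setdiff(model$states$id, state_index(model, SINK_COMPARTMENTS))
}

# tiny hand-built two/three state networks used by the core tests
chain_model <- function(k = 1, fraction = 1) {
  model_instance(
    states = list(
      species_state(1, "blood", "BHB", amount = 10),
      species_state(2, "tissues", "BHB", amount = 0)
    ),
    processes = list(
      flux_process("a_to_b", "first_order", source = 1, target = 2,
                   rate_constant = k, fraction = fraction)
    )
  )
}
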