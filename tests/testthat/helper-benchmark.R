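# The shared small-scale benchmark: 4 channels (2 low-HF, 2 high-HF) x
# {0,5,10,15} dB x 5 realizations x 120 s, all five detectors. Built once
# (lazily) and reused by the acceptance tests.

acceptance_benchmark <- function() {
  fixture("acceptance_benchmark", function() {
    models <- synthetic_channel_models(2, 2, fx_fs)
    dict <- make_default_dictionary(fx_fs, seed = derive_seed(7, "dict"))
    config <- sim_config(duration_s = 120, n_realizations = 5,
                         snr_grid_db = c(0, 5, 10, 15), fs = fx_fs, seed = 7)
    results <- run_benchmark(models, dict, config)
    benchmark_report(results)
  })
}
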