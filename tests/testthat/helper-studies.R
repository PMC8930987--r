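# Reduced-size study fixtures shared between the experiment tests and the
# acceptance property suite.

length_ablation_small <- function() {
  cached("ablation_small", {
    run_length_ablation(lengths_m = c(100, 400, 1000), n_train = 500,
                        n_test = 120, seed = 3, basis = paper_basis(),
                        config = decoder_config("linear",
                                                ridge_lambda = 0.1))
  })
}

robustness_small <- function() {
  cached("robustness_small", {
    run_robustness(strengths = c(0, 0.5, 1), delay_jitter_ps = 30,
                   joint_training = TRUE, n_train = 400, n_test = 100,
                   seed = 4, basis = paper_basis(),
                   config = decoder_config("linear", ridge_lambda = 0.1),
                   fidelity_floor = 0.70)
  })
}
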