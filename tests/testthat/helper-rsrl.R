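## Shared test seed, fixed a priori for all stochastic assertions.
TEST_SEED <- 1L
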