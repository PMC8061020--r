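# Frozen regression values for seed-determined benchmarks: recorded from the
# implementation at the stated seed, asserted to guard against silent drift.

# loocv(default synthetic benchmark, default config, seed = 7)
LOOCV_REGRESSION_AUC <- 0.468504079127861
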