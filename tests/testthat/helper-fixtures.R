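# Shared fixtures: small cohorts and noiseless measurement sets built in
# code at test time.

make_cohort <- function(n = 12, seed = 42, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}

# Noiseless records: the only error source left is 0.1-mm rounding.
noiseless_records <- function(cohort, n_sessions = 3) {
  measure_cohort(cohort, observer_noise(sd = 0, bias = 0),
                 n_sessions = n_sessions, seed = 1)
}
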