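# Demonstration cohort: 1,000 dogs over two 292-day periods.
# Any field of cohort_config() may be set here; unset fields use defaults.
n_dogs: 1000
period_start: "2019-01-02"
period_length_days: 292
n_periods: 2
rng_seed: 20190102
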