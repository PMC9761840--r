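# synthetic time-to-death bioassay: 5 concentrations, 20 fish each (pooled
# duplicates of 10), hourly counts over 96 h
a: 6.0
b: -2.0
slope: 3.0
concentrations: [2, 3, 4.5, 6.5, 9]
n_per_group: 20
study_end: 96
seed: 42
chemical: synthetic-toxicant
species: fish
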