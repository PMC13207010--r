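# Quickstart pipeline configuration: a reduced synthetic panel fitted
# with the NB model under the default prior set.
simulate:
  n_locations: 6
  years: [2014, 2016]
  family: NB
  seed: 42
families: [NB]
prior_sets: [set1]
year_effect: rw1
ndraws: 600
seed: 1
figures: true
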