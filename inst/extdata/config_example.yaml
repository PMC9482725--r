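# Example neocalib configuration (all keys optional; defaults shown).
engine: event            # event | cycle
sex: male                # male | female
cohort:
  n_individuals: 1000
  birth_year: 1949
  end_age: 79
space:
  rel: 0.2               # +/-20% search range per parameter
  rel_delta: 0.4         # +/-40% for event-engine delta_i
loss:
  w_non: 1
  w_adv: 1
  w_crc: 4
phase1:
  n_lhs: 100             # LHS designs screened (cycle engine)
  n_grid: 5              # grid nodes per dimension (event engine, stage 1)
  n_orth: 10             # orthogonal sample size per pair stage
phase2:
  strategy: two-phase-seq  # direct | two-phase-full | two-phase-seq
  effort: 100              # total design evaluations, both phases
  R: 1                     # replications averaged per evaluation
benchmark:
  efforts: [100]
  n_runs: 10
  R_targets: 1
  R_search: 1
  R_report: 10
  crn: false
seed: 1
# targets: path/to/targets.csv      # omit to generate synthetic targets
# life_table: path/to/lifetable.csv # omit for the packaged synthetic table
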