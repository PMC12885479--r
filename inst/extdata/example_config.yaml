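# Example mtctt pipeline configuration (YAML). Unset keys fall back to the
# package defaults; run validate_config() to see the fully expanded form.
seed: 1
lattice:
  n_protofilaments: 13
  n_starts: 3
  n_rings: 3
  nucleotide_state: GDP   # GDP lattice is untwisted and can be periodic
  periodic: true
criteria:
  mode: cg
  cutoff: 6.0             # bead-bead salt-bridge cutoff, Angstrom
  include_cterm_carboxylate: false
stats:
  qualifying_set: [445, 446, 447, 449, 450]
  smoothing_window: 0
  rate_estimator: occupancy
simulate:
  preset: gdp             # gdp or gtp (suppresses site-2/4 wells)
  n_sweeps: 10000
  frame_stride: 10
paths:
  out_dir: mtctt_run
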