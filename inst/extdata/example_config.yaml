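# Example pipeline configuration. Structure paths are relative to where the
# pipeline is run; chains and residue ranges for a real capsid comparison
# must be transcribed from the publication describing the structure set.
structures:
  - path: structures/virusA.pdb
    chain: A
    label: virusA
  - path: structures/virusB.pdb
    chain: A
    label: virusB
  - path: structures/virusC.pdb
    chain: B
    label: virusC
core_table: core_table.tsv
mode: core          # or full_length
clades:
  clade1: [virusA, virusB]
output_dir: run_out
seed: 1
align:
  d0: 3.0
  pair_cutoff: 6.0
  seed_window: 30
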