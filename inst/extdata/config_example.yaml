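# Example kisfold run configuration; unknown keys are rejected.
lattice:
  bond_length: 3.9    # Angstrom per virtual bond
  cap: 12             # exhaustive-enumeration cap, nt
geometry:
  virtual_bond_length: 3.9
  clash_distance: 3.5
  helix:
    rise: 2.7
    radius: 9.9
    bp_per_turn: 11
energetics:
  temperature: 310.15 # K
  c0: 0               # FJC reference constant, kcal/mol
  fjc:
    a: 6.2            # single-stranded segment, Angstrom
    b: 15             # helix-crossing segment, Angstrom
ensemble:
  ct: 1.0e-6          # total strand concentration, mol/L
  dg_init: 4.1        # association initiation, kcal/mol
  min_helix: 3
  min_hairpin: 3
  max_kissing: 1
  cap: 30
seed: 1
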