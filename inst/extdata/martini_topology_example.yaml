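# Example topology map for Martini-style bead names (template; adjust masses
# and entries to your force field before use). Species come from residue
# names in the coordinate file; a "SPECIES:BEAD" key overrides a plain bead
# name where the same bead name plays different roles in different lipids.
beads:
  NC3: {group: lipid_head, mass: 72}
  PO4: {group: lipid_head, mass: 72}
  GL1: {group: lipid_glycerol, mass: 54}
  GL2: {group: lipid_glycerol, mass: 54}
  C1A: {group: lipid_tail, mass: 72}
  C2A: {group: lipid_tail, mass: 72}
  C3A: {group: lipid_tail, mass: 72}
  C4A: {group: lipid_tail, mass: 72}
  C1B: {group: lipid_tail, mass: 72}
  C2B: {group: lipid_tail, mass: 72}
  C3B: {group: lipid_tail, mass: 72}
  C4B: {group: lipid_tail, mass: 72}
  C5B: {group: lipid_tail, mass: 72}
  D2A: {group: double_bond, mass: 72}
  D2B: {group: double_bond, mass: 72}
  D3A: {group: double_bond, mass: 72}
  D3B: {group: double_bond, mass: 72}
  CF:  {group: fullerene, mass: 45}
  W:   {group: water, mass: 72}
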