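# Default geometric criteria for typed residue interactions (version 1).
# Distances in Angstrom, angles in degrees. See ?interaction_criteria.
hbond_dist: 3.5
hbond_angle: 120.0
salt_dist: 4.0
vdw_slack: 0.5
pipi_dist: 6.5
catpi_dist: 6.0
seq_sep: 2
version: "1"
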