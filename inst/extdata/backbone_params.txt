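# Backbone heavy-atom geometry for conformer enumeration.
# Bond lengths and angles: standard protein backbone values
# (Engh & Huber-style restraint targets). van der Waals radii: Bondi.
# All values user-overridable; see ?load_params for the format.

# bond  atom1 atom2  length(A)
bond N  CA 1.458
bond CA C  1.525
bond C  N  1.329
bond C  O  1.231
bond CA CB 1.521

# angle  atom1 atom2 atom3  degrees
angle C  N  CA 121.7
angle N  CA C  111.2
angle CA C  N  116.2
angle CA C  O  120.8
angle O  C  N  123.0
angle N  CA CB 110.4
angle C  CA CB 110.5

# trans peptide torsion (degrees); cis-proline unsupported by default
omega 180.0

# improper  a b c d  target(deg); "+" prefix = atom of the next residue.
# CA N C CB fixes L-chirality at the alpha carbon (value derived from the
# bond angles above); O CA C +N fixes peptide-group planarity.
improper CA N C CB -33.84
improper O  CA C +N 180.0

# radius  element  r(A)
radius C 1.70
radius N 1.55
radius O 1.52
radius S 1.80
radius H 1.20
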