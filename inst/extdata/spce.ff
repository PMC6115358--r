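# Rigid three-site extended simple point charge water (SPC/E).
# Units: nm, kJ/mol, g/mol, e, degrees. Bond convention E = k (r - r0)^2.
# The molecule is rigid: geometry is enforced by constraints, so no [bonds].
[atoms]
# label  mass     charge   sigma   epsilon  hb_role
OW  15.9994  -0.8476  0.3166  0.650  donor_O,acceptor
HW   1.008    0.4238  0.0     0.0    donor_H
[geometry]
r_OH 0.1
angle_HOH 109.47
[meta]
# self-polarization energy of the effective-pair model, kJ/mol per molecule,
# added when reporting cohesive energies on the experimental scale
polarization_correction 5.22
# bulk saturation vapor pressure of this model at 300 K, Pa
P0_300K 1017
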