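# Bead-spring amorphous polymer host ("cellulose surrogate").
# One repeat unit = backbone bead CB + hydroxyl oxygen OH + hydroxyl hydrogen HO,
# standing in for one hydroxyl-bearing polysaccharide segment (a glucopyranose
# ring carries three hydroxyls, so one repeat unit maps to about a third of a
# ring; "per repeat unit" normalizations correspond to "per hydroxyl site").
# Charges: strongly polar hydroxyl (O -0.85, H +0.50, backbone +0.35), each
# repeat unit neutral; the hydroxyl H carries a small LJ core (CHARMM-style)
# so exposed donors cannot Coulomb-collapse onto acceptor oxygens.
# Units: nm, kJ/mol, g/mol, e, rad.
# Conventions: E_bond = k (r - r0)^2, E_angle = k (theta - theta0)^2.
[atoms]
# label  mass     charge   sigma   epsilon  hb_role
CB 70.0     0.350  0.36   0.8   none
OH  15.9994 -0.850  0.312  0.71  donor_O,acceptor
HO   1.008   0.500  0.08   0.19  donor_H
[bonds]
# i  j    k        r0
CB CB 10000 0.36
CB OH 20000 0.20
OH HO 40000 0.0945
[angles]
# i  j  k   ktheta  theta0
# semi-flexible backbone; the dry matrix is arrested by its hydroxyl
# hydrogen-bond network rather than by chain stiffness
CB CB CB 80 2.618
CB CB OH 100 1.571
CB OH HO 30 1.911
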