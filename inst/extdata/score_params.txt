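# Scoring parameter set: soft 12-6 van der Waals, distance-dependent
# dielectric electrostatics, knowledge-based atom-contact potential.
# Edit freely; readScoreParams() documents the grammar. Units: sigma in
# Angstrom, epsilon and contact values in arbitrary kcal/mol-like units.

# vdw ELEMENT sigma epsilon
vdw C 3.40 0.12
vdw N 3.25 0.16
vdw O 3.00 0.20
vdw S 3.60 0.25
vdw P 3.70 0.20

# charge RESNAME ATOM q  (unit charges on standard charged groups)
charge ASP OD1 -0.5
charge ASP OD2 -0.5
charge GLU OE1 -0.5
charge GLU OE2 -0.5
charge LYS NZ 1.0
charge ARG NH1 0.5
charge ARG NH2 0.5

# contact CLASS1 CLASS2 value  (classes: Cn Cp N O S; symmetric)
contact Cn Cn -0.30
contact Cn Cp -0.10
contact Cn N 0.10
contact Cn O 0.10
contact Cn S -0.15
contact Cp Cp -0.10
contact Cp N -0.10
contact Cp O -0.10
contact Cp S -0.05
contact N N 0.20
contact N O -0.50
contact N S -0.05
contact O O 0.20
contact O S -0.05
contact S S -0.30

# interaction cutoffs, Angstrom
cutoff vdw 8.0
cutoff elec 12.0
cutoff contact 4.5

# vdW linear clash cap starts below clash_cap_frac * sigma
clash_cap_frac 0.6

# fitness weights
weight vdw 1
weight elec 1
weight contact 1
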