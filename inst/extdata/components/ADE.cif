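data_ADE
# adenine (9H-purine-6-amine), Kekule bond orders
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
ADE N1 N 0
ADE C2 C 0
ADE N3 N 0
ADE C4 C 0
ADE C5 C 0
ADE C6 C 0
ADE N6 N 0
ADE N7 N 0
ADE C8 C 0
ADE N9 N 0
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_order
ADE N1 C2 DOUB
ADE C2 N3 SING
ADE N3 C4 DOUB
ADE C4 C5 SING
ADE C5 C6 DOUB
ADE C6 N1 SING
ADE C6 N6 SING
ADE C5 N7 SING
ADE N7 C8 DOUB
ADE C8 N9 SING
ADE N9 C4 SING
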