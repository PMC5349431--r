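data_GOL
# glycerol
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
GOL C1 C 0
GOL O1 O 0
GOL C2 C 0
GOL O2 O 0
GOL C3 C 0
GOL O3 O 0
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_order
GOL C1 O1 SING
GOL C1 C2 SING
GOL C2 O2 SING
GOL C2 C3 SING
GOL C3 O3 SING
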