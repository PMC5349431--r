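data_ACT
# acetate ion
loop_
_chem_comp_atom.comp_id
_chem_comp_atom.atom_id
_chem_comp_atom.type_symbol
_chem_comp_atom.charge
ACT C C 0
ACT O O 0
ACT OXT O -1
ACT CH3 C 0
loop_
_chem_comp_bond.comp_id
_chem_comp_bond.atom_id_1
_chem_comp_bond.atom_id_2
_chem_comp_bond.value_order
ACT C O DOUB
ACT C OXT SING
ACT C CH3 SING
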