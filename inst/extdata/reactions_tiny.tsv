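C=CC(C(C)C)C(C)C.O>>CC(C(C(O)C)C(C)C)C	1
OCCC(C(CC)C)(C)C.CCCC(C(=O)O)(C(C)C)CC>>CCCC(C(=O)OCCC(C(CC)C)(C)C)(C(C)C)CC.O	3
CCCCCC(CC(CCO)O)C>>CCCCCC(CC1CCO1)C.O	4
CCC(C(C=C)(C)C)C(C)C.O>>CCC(C(C(O)C)(C)C)C(C)C	1
CC(CC(C1CCCO1)CC(C)C)C.O>>OCCCC(C(CC(C)C)CC(C)C)O	2
OCCCC(C(CC(C)C)CC(C)C)O>>CC(CC(C1CCCO1)CC(C)C)C.O	4
CCCCCC(CC1CCO1)C.O>>CCCCCC(CC(CCO)O)C	2
CC(C(CC(O)(C)C)C)C.CCCC(C(C(=O)O)(C)C)C>>CCCC(C(C(=O)OC(CC(C(C)C)C)(C)C)(C)C)C.O	3
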