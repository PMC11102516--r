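smiles,n_bits,radius,popcount,on_bits
CCO,256,3,6,33;38;39;80;130;222
c1ccccc1,256,3,4,64;81;133;208
CC(=O)Oc1ccccc1C(=O)O,256,3,31,
CN1CCC[C@H]1c1cccnc1,256,3,35,
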