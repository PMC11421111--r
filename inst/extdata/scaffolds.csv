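scaffold_name,smiles
chromone,O=C1C=COc2ccccc21
xanthone,O=C1c2ccccc2Oc2ccccc21
phenothiazine,N1c2ccccc2Sc2ccccc21
purine,c1ncc2[nH]cnc2n1
deazapurine,c1ncc2cc[nH]c2n1
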