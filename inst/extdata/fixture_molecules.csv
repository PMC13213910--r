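ligand_id,smiles,expected_failed_rule
clean_piperazine,CC(=O)Nc1ccc(cc1)N1CCN(CC1)c1ccccc1,
clean_ether_amide,CCOc1ccc(cc1)C(=O)Nc1ccc(C)cc1OC,
clean_sulfonamide,Cc1ccc(cc1)S(=O)(=O)Nc1ccc(OC)cc1,
mw_low,CC(=O)Oc1ccccc1C(=O)O,mw_range
rot_flexible,c1ccccc1OCCOCCOCCOCCOCCOCCOc1ccccc1,rot_bonds
phosphorus_tpp,c1ccc(cc1)P(c2ccccc2)c3ccccc3,phosphorus
ionizable_triacid,OC(=O)c1ccc(cc1)c1cc(C(=O)O)cc(C(=O)O)c1,ionizable
no_ring_ester,CCOC(=O)C(C)OC(=O)C(C)OC(=O)CC(C)C,no_ring
long_chain_diamide,O=C(N1CCOCC1)c1ccc(cc1)CCCCCCCCC(=O)N1CCOCC1,long_chain
fused_ring_steroid,CC12CCC3C(C1CCC2O)CCC4CC(O)CCC34C,fused_rings
reactive_aldehyde,O=Cc1ccc(cc1)N1CCN(CC1)c1ccccc1,reactive
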