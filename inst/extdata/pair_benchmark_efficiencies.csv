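pair,E_pct_5nm,E_pct_6nm,E_pct_7nm
Clv-mCh,55,29,14
Clv-mR2,69,43,23
EGFP-mCh,43,20,9
EGFP-mR2,58,32,16
mTFP-sRCh,64,37,19
mTFP-Ven,59,32,16
mTFP-YPet,61,35,17
mTq2-sRCh,61,34,17
mTq2-Ven,55,29,14
mTq2-YPet,58,32,16
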