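pair,donor,acceptor,qy_donor,J,r0_ref
Clv-mCh,Clv,mCh,0.76,2.50e15,5.18
Clv-mR2,Clv,mR2,0.76,4.51e15,5.71
EGFP-mCh,EGFP,mCh,0.60,1.94e15,4.77
EGFP-mR2,EGFP,mR2,0.60,3.61e15,5.29
mTFP-sRCh,mTFP1,sRCh,0.85,3.19e15,5.50
mTFP-Ven,mTFP1,Ven,0.85,2.56e15,5.30
mTFP-YPet,mTFP1,YPet,0.85,2.89e15,5.40
mTq2-sRCh,mTq2,sRCh,0.93,2.54e15,5.37
mTq2-Ven,mTq2,Ven,0.93,2.04e15,5.18
mTq2-YPet,mTq2,YPet,0.93,2.30e15,5.28
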