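pair,mode,Zprime_FD,Zprime_FD_sd,E_pct_FD,E_pct_FD_sd,Zprime_TD,Zprime_TD_sd,E_pct_TD,E_pct_TD_sd
Clv-mCh,static,0.684,0.003,24.1,2.5,0.645,0.086,24.19,2.12
Clv-mR2,static,-0.778,1.316,12.1,6.5,-0.300,0.163,13.27,2.68
EGFP-mCh,static,0.488,0.080,20.7,0.9,0.425,0.172,18.68,2.00
EGFP-mR2,static,-0.725,0.212,8.5,1.0,-0.592,0.078,10.26,1.99
mTFP-sRCh,static,0.631,0.073,34.4,1.0,0.675,0.127,35.93,4.74
mTFP-Ven,static,0.640,0.081,34.1,0.7,0.653,0.140,37.58,4.01
mTFP-YPet,static,0.617,0.073,33.1,0.6,0.324,0.195,36.55,1.39
mTq2-sRCh,static,0.655,0.143,30.5,1.8,0.610,0.021,30.86,3.35
mTq2-Ven,static,0.437,0.047,26.9,1.5,0.623,0.078,32.19,2.25
mTq2-YPet,static,0.011,0.347,33.2,4.0,-1.317,0.573,26.82,4.16
Clv-mCh,dynamic,0.684,0.012,24.12,2.29,0.642,0.096,23.6,2.3
Clv-mR2,dynamic,-0.888,1.592,12.01,7.12,-0.264,0.321,12.6,3.4
EGFP-mCh,dynamic,0.498,0.058,20.50,0.91,0.420,0.183,18.7,1.7
EGFP-mR2,dynamic,-0.728,0.259,8.28,2.09,-0.835,0.101,8.7,1.3
mTFP-sRCh,dynamic,0.740,0.011,35.28,0.63,0.482,0.168,34.8,3.1
mTFP-Ven,dynamic,0.583,0.042,32.99,1.06,0.604,0.127,37.2,4.6
mTFP-YPet,dynamic,0.536,0.071,28.68,0.14,0.192,0.252,37.1,1.0
mTq2-sRCh,dynamic,0.777,0.026,34.08,0.57,0.552,0.049,29.6,1.3
mTq2-Ven,dynamic,0.395,0.081,25.78,1.52,0.557,0.091,30.8,1.5
mTq2-YPet,dynamic,-0.095,0.305,26.98,3.26,-1.354,0.561,27.4,6.4
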