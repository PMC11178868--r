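target,horizon_h,k_cut,P,E,e,U,r,d
Psy1,72,0.0092,0.0791,0.0335,0.2052,0,9402.089,0
CRTISO,72,0.0175,0.0675,0.0777,0.32,0,48.831,0
PhyB2,72,0.0718,0.0583,0.0864,0.0817,0.4047,8.0297,0
Psy1,24,0.0164,0.0691,0.0777,0.1228,0,12336.241,0
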