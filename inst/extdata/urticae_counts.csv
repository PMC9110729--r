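id,treatment,excluded,sex,death_stage,death_age,egg,L1,L2,L3,L4,prepupa,pupa,adult
f01,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f02,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f03,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f04,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f05,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f06,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f07,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f08,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f09,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f10,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f11,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f12,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f13,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f14,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f15,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f16,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f17,t_urticae,FALSE,female,adult,113,3,2,2,3,4,1,4,94
f18,t_urticae,FALSE,female,adult,112,3,2,2,3,4,1,3,94
f19,t_urticae,FALSE,female,adult,112,3,2,2,3,4,1,3,94
f20,t_urticae,FALSE,female,adult,112,3,2,2,3,4,1,3,94
f21,t_urticae,FALSE,female,adult,112,3,2,2,3,4,1,3,94
f22,t_urticae,FALSE,female,adult,112,3,2,2,3,4,1,3,94
f23,t_urticae,FALSE,female,adult,112,3,2,2,3,4,1,3,94
f24,t_urticae,FALSE,female,adult,111,3,2,2,3,4,1,3,93
f25,t_urticae,FALSE,female,adult,111,3,2,2,3,4,1,3,93
m01,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m02,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m03,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m04,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m05,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m06,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m07,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m08,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m09,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m10,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m11,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m12,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m13,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m14,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m15,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m16,t_urticae,FALSE,male,adult,109,3,2,2,3,4,1,4,90
m17,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
m18,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
m19,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
m20,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
m21,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
m22,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
m23,t_urticae,FALSE,male,adult,108,3,2,2,3,4,1,3,90
x01,t_urticae,FALSE,undetermined,pupa,17,3,2,2,3,4,1,2,
x02,t_urticae,FALSE,undetermined,pupa,17,3,2,2,3,4,1,2,
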