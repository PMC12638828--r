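subject,session,trial,stimulus_id,context
m1,m1_motion_s01,1,s01,motion
m1,m1_motion_s01,2,s01,motion
m1,m1_motion_s01,3,s02,motion
m1,m1_motion_s01,4,s02,motion
m1,m1_motion_s01,5,s03,motion
m1,m1_motion_s01,6,s03,motion
m1,m1_motion_s01,7,s04,motion
m1,m1_motion_s01,8,s04,motion
m1,m1_motion_s01,9,s05,motion
m1,m1_motion_s01,10,s05,motion
m1,m1_motion_s01,11,s06,motion
m1,m1_motion_s01,12,s06,motion
m1,m1_motion_s01,13,s07,motion
m1,m1_motion_s01,14,s07,motion
m1,m1_motion_s01,15,s08,motion
m1,m1_motion_s01,16,s08,motion
m1,m1_motion_s01,17,s09,motion
m1,m1_motion_s01,18,s09,motion
m1,m1_motion_s01,19,s10,motion
m1,m1_motion_s01,20,s10,motion
m1,m1_motion_s01,21,s11,motion
m1,m1_motion_s01,22,s11,motion
m1,m1_motion_s01,23,s12,motion
m1,m1_motion_s01,24,s12,motion
m1,m1_motion_s01,25,s13,motion
m1,m1_motion_s01,26,s13,motion
m1,m1_motion_s01,27,s14,motion
m1,m1_motion_s01,28,s14,motion
m1,m1_motion_s01,29,s15,motion
m1,m1_motion_s01,30,s15,motion
m1,m1_motion_s01,31,s16,motion
m1,m1_motion_s01,32,s16,motion
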