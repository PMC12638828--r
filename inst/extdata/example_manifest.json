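{"window":[-0.1,0.5],"sessions":"m1_motion_s01","sites":[["site01","site02","site03"]]}
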