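"TRACK_ID","FRAME","POSITION_T","POSITION_X","POSITION_Y","MEAN_INTENSITY"
0,0,0,100,0,52
0,1,0.5,99,0,52
0,2,1,98,0,52
1,0,0,50,0,52
1,1,0.5,50.1,0,52
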