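pair,FP1,FP2,F3,F4,F7,F8,Fz,C3,C4,T3,T4,Pz
anger-calm,146,135,139,144,136,112,138,130,125,94,168,152
anger-joy,132,116,107,130,109,105,115,126,76,92,157,142
anger-sad,99,126,83,99,100,97,100,117,66,67,120,127
calm-joy,126,124,101,116,97,119,121,109,99,80,124,129
calm-sad,161,151,127,138,151,133,137,149,126,107,179,164
joy-sad,112,127,94,111,116,110,103,127,89,103,162,145
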