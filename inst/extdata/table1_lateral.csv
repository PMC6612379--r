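Shift,CL,CLR,CLL
No Change,5,1,1
To the RIGHT,8,6,14
To the Left,7,13,5
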