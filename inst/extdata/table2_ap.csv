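Shift,CL-LF,CL-RF,CLR-LF,CLR-RF,CLL-LF,CLL-RF
No Change,2,4,5,4,2,3
To Anterior,12,7,7,7,11,12
To Posterior,6,9,8,9,7,5
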