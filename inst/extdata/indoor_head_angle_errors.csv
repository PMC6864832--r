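true_deg,error_deg
10,1.9
20,4.3
30,6.1
40,7.3
50,4.1
60,0.9
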