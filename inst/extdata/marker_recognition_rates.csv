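marker_id,marker,rate_pct
1,triangle_up,93.9
2,circle,87.5
3,triangle_down,91.4
4,star,88.2
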