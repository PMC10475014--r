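phase_h_after_dlmo,shift_h
1,-0.3
2,-0.5
3,-0.7
4,-0.9
5,-1.1
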