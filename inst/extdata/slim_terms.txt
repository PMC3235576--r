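FX:0000100
FX:0000200
FX:0000300
FX:0000400
FX:0000600
FX:0000450
FX:0000470
FX:0000500
FX:0000700
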