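assay,concentration,a0,a1
dpph,5,0.7,0.5109
dpph,10,0.7,0.3712
dpph,15,0.7,0.2634
dpph,20,0.7,0.1958
dpph,25,0.7,0.1566
dpph,30,0.7,0.1267
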