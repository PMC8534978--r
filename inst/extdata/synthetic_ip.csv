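sample,temperature,temperature_unit,ip_hours
OA,100,C,1.399
OA,110,C,0.972
OA,120,C,0.635
OA,130,C,0.452
CA + OA,100,C,2.073
CA + OA,110,C,1.338
CA + OA,120,C,0.743
CA + OA,130,C,0.46
TBHQ + OA,100,C,1.862
TBHQ + OA,110,C,1.124
TBHQ + OA,120,C,0.684
TBHQ + OA,130,C,0.471
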