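sample,beta_K_per_min,tp,tp_unit
OA,5,494.61,K
OA,10,522.78,K
OA,15,540.79,K
OA,20,554.34,K
CA + OA,5,501.87,K
CA + OA,10,529.57,K
CA + OA,15,547.24,K
CA + OA,20,560.51,K
TBHQ + OA,5,497.51,K
TBHQ + OA,10,525.32,K
TBHQ + OA,15,543.07,K
TBHQ + OA,20,556.41,K
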