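laterality,gt,MM_mucus,MT_mucus
left,positive,30,32
left,negative,1,2
right,positive,6,31
right,negative,1,7
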