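region,n,sensitivity,specificity,precision,accuracy,f1
left,96,78.5,82.4,95.4,79.2,86.1
right,82,69.8,72.4,82.2,70.7,75.5
overall,178,75.0,76.0,90.0,75.2,81.8
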