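dimension,n,mean_pct,se_pct
structure,400,51.7,0.88
core,400,20.0,0.56
supportive,400,38.4,1.01
attributes,400,69.6,0.81
overall,400,44.9,0.52
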