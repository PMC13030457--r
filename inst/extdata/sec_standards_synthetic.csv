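name,rh,elution
ribonuclease_a,1.75,11.95
myoglobin,1.9,11.76
ovalbumin,2.8,10.85
aldolase,4.8,9.59
thyroglobulin,8.6,8.22
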