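"surface","total","surface_iso","total_iso"
620,2030,20,38.3
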