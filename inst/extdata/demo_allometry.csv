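species,a,b,form
Castanopsis wattii,0.03086,0.9696,compound
*,0.0509,0.93,compound
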