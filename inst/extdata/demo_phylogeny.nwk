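(((Castanopsis_wattii:0.18,Lithocarpus_hancei:0.18):0.52,(Machilus_gamblei:0.35,Cinnamomum_chago:0.35):0.35):0.30,Vaccinium_duclouxii:1.00);
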