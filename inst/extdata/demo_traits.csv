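species,SLA,LN,LP,LK,LC
Castanopsis wattii,11.8,17.2,1.21,6.4,478
Lithocarpus hancei,10.5,15.9,1.05,5.8,465
Machilus gamblei,14.9,21.3,1.48,8.2,452
Cinnamomum chago,16.2,22.8,1.62,9.1,447
Vaccinium duclouxii,13.1,18.4,1.30,7.3,490
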