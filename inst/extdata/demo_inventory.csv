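plot_id,species,dbh,height
p1,Castanopsis wattii,32.5,21.0
p1,Castanopsis wattii,12.1,11.2
p1,Lithocarpus hancei,24.0,17.5
p1,Machilus gamblei,4.2,4.1
p1,Cinnamomum chago,2.8,3.2
p2,Castanopsis wattii,45.3,23.5
p2,Lithocarpus hancei,8.7,7.9
p2,Machilus gamblei,15.6,13.0
p2,Vaccinium duclouxii,1.9,2.4
p3,Lithocarpus hancei,28.4,18.8
p3,Machilus gamblei,9.0,8.8
p3,Cinnamomum chago,6.5,5.9
p3,Vaccinium duclouxii,3.3,3.5
p4,Castanopsis wattii,19.8,15.2
p4,Cinnamomum chago,11.4,10.6
p4,Vaccinium duclouxii,2.2,2.7
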