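plot_id,elevation,slope,aspect,pH,SOM,TN,TP,TK,AN,AP,AK,AB
p1,2481,14.5,135,4.42,93.5,4.8,0.91,16.2,0.34,0.021,0.18,0.0012
p2,2539,22.0,210,4.55,71.2,3.9,0.74,13.8,0.27,0.017,0.13,0.0009
p3,2587,9.8,88,4.61,84.0,4.3,0.83,15.1,0.31,0.024,0.16,0.0011
p4,2622,27.3,300,4.48,66.8,3.5,0.69,12.9,0.24,0.015,0.12,0.0008
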