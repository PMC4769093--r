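identity,mass,charge,reference_ccs,observed_drift
cal1,1200,2,337.576016290,2.4
cal2,2800,3,579.251903086,3.1
cal3,4600,4,875.378261888,3.9
cal4,6800,5,1197.685636328,4.6
cal5,8500,6,1537.786873277,5.2
cal6,10200,7,1923.765725998,5.9
cal7,11800,7,2080.318249160,6.8
cal8,14300,8,2527.904708061,7.6
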