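sequence,roi_kind,mean_roi_sd,units
T1,WK,354.1,ms
T1,Cx,125.7,ms
T1,repCx,49.6,ms
T1,supCx,71.4,ms
T1,infCx,69.8,ms
T1,Med,74.9,ms
pCASL,WK,100.7,ml/100 g/min
pCASL,Cx,85.1,ml/100 g/min
pCASL,repCx,41.2,ml/100 g/min
pCASL,supCx,48.0,ml/100 g/min
pCASL,infCx,53.2,ml/100 g/min
pCASL,Med,41.8,ml/100 g/min
ADC,WK,289.5,1e-6 mm^2/s
ADC,Cx,169.6,1e-6 mm^2/s
ADC,repCx,71.5,1e-6 mm^2/s
ADC,supCx,105.8,1e-6 mm^2/s
ADC,infCx,85.9,1e-6 mm^2/s
ADC,Med,84.7,1e-6 mm^2/s
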