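sequence,roi_kind,group,n,mean,sd,units
volume_alternate,WK,All,39,195.8,56.8,ml
volume_alternate,WK,HV,10,147.8,30.9,ml
volume_alternate,WK,HF,10,170.6,45.3,ml
volume_alternate,WK,Tx,20,230.1,49.2,ml
volume_every,WK,All,39,197.5,57.4,ml
volume_every,WK,HV,10,149.0,31.3,ml
volume_every,WK,HF,10,170.8,44.9,ml
volume_every,WK,Tx,20,232.6,49.3,ml
T1,WK,All,39,1772.8,131.4,ms
T1,WK,HV,10,1702.4,76.7,ms
T1,WK,HF,10,1696.5,85.7,ms
T1,WK,Tx,20,1842.6,134.4,ms
T1,Cx,All,39,1630.2,102.0,ms
T1,Cx,HV,10,1557.7,104.1,ms
T1,Cx,HF,10,1595.5,80.1,ms
T1,Cx,Tx,20,1680.1,86.3,ms
T1,repCx,All,39,1606.1,114.4,ms
T1,repCx,HV,10,1545.4,113.2,ms
T1,repCx,HF,10,1543.8,71.1,ms
T1,repCx,Tx,20,1664.6,105.0,ms
T1,supCx,All,39,1655.6,119.5,ms
T1,supCx,HV,10,1606.8,149.8,ms
T1,supCx,HF,10,1600.0,93.4,ms
T1,supCx,Tx,20,1705.3,98.1,ms
T1,infCx,All,39,1639.0,103.7,ms
T1,infCx,HV,10,1587.0,94.3,ms
T1,infCx,HF,10,1590.0,113.3,ms
T1,infCx,Tx,20,1687.0,82.0,ms
T1,Med,All,39,1975.8,74.9,ms
T1,Med,HV,10,1899.0,80.5,ms
T1,Med,HF,10,1940.2,71.3,ms
T1,Med,Tx,20,2028.1,74.2,ms
pCASL,WK,All,37,181.7,56.6,ml/100 g/min
pCASL,WK,HV,10,187.5,58.4,ml/100 g/min
pCASL,WK,HF,10,161.6,47.1,ml/100 g/min
pCASL,WK,Tx,18,190.2,60.7,ml/100 g/min
pCASL,Cx,All,37,221.0,80.0,ml/100 g/min
pCASL,Cx,HV,10,235.1,79.3,ml/100 g/min
pCASL,Cx,HF,10,175.7,59.5,ml/100 g/min
pCASL,Cx,Tx,18,239.3,84.3,ml/100 g/min
pCASL,repCx,All,37,260.8,91.4,ml/100 g/min
pCASL,repCx,HV,10,271.8,93.5,ml/100 g/min
pCASL,repCx,HF,10,228.4,92.3,ml/100 g/min
pCASL,repCx,Tx,18,273.3,90.4,ml/100 g/min
pCASL,supCx,All,37,196.4,75.9,ml/100 g/min
pCASL,supCx,HV,10,230.5,77.9,ml/100 g/min
pCASL,supCx,HF,10,160.4,54.2,ml/100 g/min
pCASL,supCx,Tx,18,197.4,79.6,ml/100 g/min
pCASL,infCx,All,37,225.2,105.2,ml/100 g/min
pCASL,infCx,HV,10,213.8,91.1,ml/100 g/min
pCASL,infCx,HF,10,161.8,84.4,ml/100 g/min
pCASL,infCx,Tx,18,269.2,107.5,ml/100 g/min
pCASL,Med,All,37,95.8,41.8,ml/100 g/min
pCASL,Med,HV,10,108.8,45.1,ml/100 g/min
pCASL,Med,HF,10,121.5,31.5,ml/100 g/min
pCASL,Med,Tx,18,73.0,45.9,ml/100 g/min
ADC,WK,All,28,1687.6,115.6,1e-6 mm^2/s
ADC,WK,HV,10,1687.2,97.4,1e-6 mm^2/s
ADC,WK,Tx,18,1687.7,125.8,1e-6 mm^2/s
ADC,Cx,All,28,1678.1,111.4,1e-6 mm^2/s
ADC,Cx,HV,10,1704.0,96.8,1e-6 mm^2/s
ADC,Cx,Tx,18,1665.8,118.1,1e-6 mm^2/s
ADC,repCx,All,28,1696.9,117.7,1e-6 mm^2/s
ADC,repCx,HV,10,1719.9,158.6,1e-6 mm^2/s
ADC,repCx,Tx,18,1686.0,96.1,1e-6 mm^2/s
ADC,supCx,All,28,1686.3,144.2,1e-6 mm^2/s
ADC,supCx,HV,10,1720.4,120.6,1e-6 mm^2/s
ADC,supCx,Tx,18,1670.1,154.5,1e-6 mm^2/s
ADC,infCx,All,28,1696.4,115.2,1e-6 mm^2/s
ADC,infCx,HV,10,1700.5,111.8,1e-6 mm^2/s
ADC,infCx,Tx,18,1694.4,119.7,1e-6 mm^2/s
ADC,Med,All,28,1671.9,82.5,1e-6 mm^2/s
ADC,Med,HV,10,1726.3,93.9,1e-6 mm^2/s
ADC,Med,Tx,18,1646.1,77.2,1e-6 mm^2/s
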