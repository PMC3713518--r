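cell_line,condition,mean_viability,sd,n
HeLa,fiber_alone,0.40,0.05,4
HeLa,BAF1,0.66,0.04,4
HeLa,BAF4,0.93,0.13,4
HeLa,BAF8,0.54,0.06,4
HeLa,BAF11,0.69,0.07,4
HeLa,BAF12,0.63,0.04,4
HeLa,BAF26,0.68,0.14,4
HeLa,BAF30,0.51,0.08,4
HeLa,BAF31,0.91,0.07,4
PC12,fiber_alone,0.37,0.07,4
PC12,BAF1,0.61,0.07,4
PC12,BAF4,0.90,0.11,4
PC12,BAF8,0.53,0.07,4
PC12,BAF11,0.69,0.07,4
PC12,BAF12,0.49,0.04,4
PC12,BAF26,0.74,0.13,4
PC12,BAF30,0.60,0.11,4
PC12,BAF31,0.95,0.14,4
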