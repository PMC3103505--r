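subject,group,C,L,Q,E_glob,E_loc,sigma,combined
Wt1,control,0.9999,0.0093,0.8056,0.9999,0.9999,0.9999,0.9999
Wt2,control,0.9999,0.6524,0.4438,0.9999,0.9998,0.9560,0.9999
Wt3,control,0.9999,0.9724,0.5079,0.9999,0.9999,0.9990,1
Wt4,control,0.9999,0.9725,0.9162,0.9999,0.9998,0.9724,0.9999
Wt5,control,0.9838,0.7499,0.8080,0.9999,0.8183,0.9722,0.9963
Wt6,control,0.9999,0.4841,0.8383,0.9999,0.9999,0.9928,1.0000
Shi1,case,0.0179,0.9710,0.7829,0.9889,0.3150,0.0891,0.0083
Shi2,case,7.58e-10,0.0163,0.3956,1.97e-10,6.07e-7,2.00e-06,4.44e-16
Shi3,case,0.0075,0.1708,0.1862,0.0019,0.1116,0.0327,0.0009
Shi4,case,2.30e-10,0.6477,3.2287,2.30e-07,3.31e-06,0.1507,6.66e-16
Shi5,case,2.97e-12,0.0339,0.6757,0,7.10e-11,6.93e-05,0
Shi6,case,4.46e-07,0.1015,0.6455,5.15e-11,4.19e-06,0.0063,1.87e-12
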