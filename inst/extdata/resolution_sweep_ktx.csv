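pixels,edge_um,metric_auroc,infer_co2eq_g
224,1024,0.702,0.025
224,256,0.762,0.138
512,256,0.678,0.383
224,128,0.640,1.87
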