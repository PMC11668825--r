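model_id,metric_auroc,metric_balanced_accuracy,metric_precision,metric_recall,metric_f1,train_energy_kwh,train_co2eq_kg,infer_energy_wh,infer_co2eq_g
TransMIL,0.7609,0.5282,0.6542,0.5148,0.5070,11.263,4.065,0.128,0.046
CLAM,0.7436,0.4864,0.5452,0.4885,0.4748,11.713,4.228,0.132,0.048
InceptionV3,0.6732,0.2681,0.0901,0.3283,0.1404,10.584,3.821,0.201,0.073
ViT,0.6979,0.2747,0.0942,0.3331,0.1452,23.873,8.618,0.170,0.065
Prov-GigaPath,0.7149,0.4203,0.5468,0.3867,0.3379,42.625,15.388,0.63,0.229
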