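model_id,metric_auroc,metric_balanced_accuracy,metric_precision,metric_recall,metric_f1,train_energy_kwh,train_co2eq_kg,infer_energy_wh,infer_co2eq_g
TransMIL,0.9818,0.8944,0.8579,0.8337,0.8222,11.263,4.065,0.128,0.046
CLAM,0.9733,0.9077,0.9177,0.7389,0.7677,11.713,4.228,0.132,0.048
InceptionV3,0.8779,0.6893,0.7230,0.6893,0.6758,10.584,3.821,0.201,0.073
ViT,0.8768,0.8446,0.7050,0.6603,0.6407,23.873,8.618,0.170,0.065
Prov-GigaPath,0.9740,0.9075,0.8423,0.7627,0.7716,42.625,15.388,0.63,0.229
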