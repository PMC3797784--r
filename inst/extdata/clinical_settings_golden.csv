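setting,volume_ml,us_rda_default,us_rda_premenopausal,uk_rni_default,uk_rni_premenopausal
No additional losses,0,8,18,8.7,14.8
Blood donation every 3 months,470,27.6,37.6,20.6,26.7
Hemorrhagic hemoglobin fall of 1 g/dl,470,27.6,37.6,20.6,26.7
Hemorrhagic hemoglobin fall of 2 g/dl,940,47.2,57.2,32.6,38.7
Hemorrhagic hemoglobin fall of 3 g/dl,1410,66.8,76.8,44.5,50.6
Hemorrhagic hemoglobin fall of 4 g/dl,1880,86.3,96.3,56.5,62.6
Femoral head fracture,611,33.5,43.5,24.2,30.3
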