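organ,density_g_cm3
frontal_lobe_r,1.04
frontal_lobe_l,1.04
temporal_lobe_r,1.04
temporal_lobe_l,1.04
parietal_lobe_r,1.04
parietal_lobe_l,1.04
cerebellum,1.04
occipital_lobe,1.04
inner_brain,1.04
pituitary,1.04
thyroid_lobe_r,1.05
thyroid_lobe_l,1.05
heart,1.05
lung_r,0.26
lung_l,0.26
liver,1.06
stomach,1.05
pancreas,1.04
kidney_r,1.05
kidney_l,1.05
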