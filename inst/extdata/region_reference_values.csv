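region,tissue_class,ps_mean,ps_ci_low,ps_ci_high,vp_mean,vp_ci_low,vp_ci_high,ps_vp_r
frontal_cortex,cortex,0.52,0.46,0.57,1.18,1.13,1.23,0.19
parietal_cortex,cortex,0.52,0.46,0.58,1.22,1.17,1.27,0.28
temporal_cortex,cortex,0.72,0.67,0.78,1.32,1.26,1.38,0.40
occipital_cortex,cortex,0.86,0.77,0.96,1.73,1.63,1.84,0.53
cingulate_cortex,cortex,0.56,0.49,0.64,1.49,1.41,1.57,0.51
frontal_wm,white_matter,0.52,0.44,0.60,0.81,0.77,0.85,0.41
parietal_wm,white_matter,0.48,0.40,0.55,0.79,0.75,0.83,0.32
temporal_wm,white_matter,0.49,0.42,0.57,0.82,0.78,0.87,0.41
occipital_wm,white_matter,0.39,0.31,0.48,0.80,0.76,0.84,0.34
cingulate_wm,white_matter,0.58,0.49,0.68,0.91,0.86,0.97,0.51
thalamus,subcortical,0.54,0.45,0.63,1.68,1.60,1.76,0.49
caudate,subcortical,0.45,0.36,0.53,1.47,1.40,1.54,0.39
putamen,subcortical,0.66,0.58,0.72,1.65,1.58,1.72,0.24
pallidum,subcortical,0.63,0.53,0.73,1.20,1.13,1.26,0.40
hippocampus,subcortical,0.64,0.56,0.73,1.78,1.67,1.89,0.35
cortex_average,aggregate,NA,NA,NA,1.29,NA,NA,NA
white_matter_average,aggregate,NA,NA,NA,0.81,NA,NA,NA
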