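region,gt7t_cm3,gt3t_cm3,syn7t_cm3
White Matter,409.262,459.393,415.564
Grey Matter,690.165,746.664,683.018
Brain,1099.429,1206.056,1125.340
Intracranial Cavity,1355.201,1385.661,1370.616
CSF,239.683,162.003,228.795
Cerebrum,987.407,1073.781,1002.440
Cerebellum,102.823,121.333,112.559
Brainstem,16.091,17.602,16.480
Hippocampus,6.053,6.995,6.228
Thalamus,16.322,16.598,16.071
Caudate,5.804,6.398,5.752
Putamen,9.382,9.153,9.040
Amygdala,1.570,2.223,1.650
Frontal Lobe,180.514,192.400,184.646
Temporal Lobe,115.179,127.696,113.951
Parietal Lobe,107.091,116.270,109.554
Occipital Lobe,86.287,87.368,85.925
Lateral Ventricles,18.271,16.703,18.531
3rd Ventricle,0.969,0.684,0.907
4th Ventricle,1.472,1.390,1.448
External CSF,217.698,142.376,206.505
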