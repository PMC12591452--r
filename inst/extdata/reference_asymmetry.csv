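pair,gt_index,syn_index
Hippocampus,-4.7443,-1.8469
Caudate,3.6747,3.8648
Thalamus,0.6119,0.5088
Lateral Ventricles,5.7013,5.5633
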