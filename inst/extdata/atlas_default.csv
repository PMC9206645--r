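"roi","hemisphere","network"
"amygdala_left","left","SN"
"amygdala_right","right","SN"
"anterior_cingulate_left","left","SN"
"anterior_cingulate_right","right","SN"
"insula_left","left","SN"
"insula_right","right","SN"
"thalamus_left","left","SN"
"thalamus_right","right","SN"
"subthalamic_nucleus_left","left","SN"
"subthalamic_nucleus_right","right","SN"
"lentiform_nucleus_left","left","SN"
"lentiform_nucleus_right","right","SN"
"posterior_cingulate_left","left","DMN"
"posterior_cingulate_right","right","DMN"
"hippocampus_left","left","DMN"
"hippocampus_right","right","DMN"
"parahippocampal_anterior_left","left","DMN"
"parahippocampal_anterior_right","right","DMN"
"parahippocampal_posterior_left","left","DMN"
"parahippocampal_posterior_right","right","DMN"
"fusiform_anterior_left","left","DMN"
"fusiform_anterior_right","right","DMN"
"fusiform_posterior_left","left","DMN"
"fusiform_posterior_right","right","DMN"
"frontal_lobe_left","left","ECN"
"frontal_lobe_right","right","ECN"
"parietal_lobe_left","left","ECN"
"parietal_lobe_right","right","ECN"
"cerebellum_left","left","ECN"
"cerebellum_right","right","ECN"
"caudate_nucleus_left","left","ECN"
"caudate_nucleus_right","right","ECN"
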