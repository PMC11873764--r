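region_1	region_2	p_fdr_published	p_raw	ewd
Thalami/Brainstem	Salience	0.0104	0.0005	0.1427
Thalami/Brainstem	Sensorimotor	0.0214	0.0020	0.1127
Thalami/Brainstem	Auditory	0.0368	0.0064	0.0934
Thalami/Brainstem	Prefrontal	0.0403	0.0081	0.0994
Thalami/Brainstem	ACC vmPFC Amygdala	0.0331	0.0048	0.0865
ACC vmPFC Amygdala	Visual	0.0329	0.0042	0.1058
ACC vmPFC Amygdala	Cerebellum	0.0368	0.0067	0.1
ACC vmPFC Amygdala	Left Precuneus	0.0403	0.0088	0.0987
Salience	Visual	0.0210	0.0015	0.1212
Salience	Cerebellum	0.0214	0.0023	0.1148
Sensorimotor	Auditory	0.0029	5.40E-05	0.1377
Sensorimotor	Bilateral PCC	0.0104	0.0006	0.1177
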