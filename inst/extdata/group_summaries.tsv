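variable	roi	side	m_patient	sd_patient	m_control	sd_control
FA	optic_tract	left	0.291	0.019	0.392	0.043
FA	optic_tract	right	0.288	0.038	0.376	0.037
FA	chiasm	both	0.166	0.047	0.28	0.064
FA	optic_nerve	left	0.266	0.044	0.338	0.047
FA	optic_nerve	right	0.233	0.051	0.362	0.057
MD	optic_tract	left	1.61	0.09	1.55	0.10
MD	optic_tract	right	1.64	0.21	1.57	0.13
MD	chiasm	both	1.77	0.37	1.76	0.24
MD	optic_nerve	left	1.47	0.18	1.50	0.29
MD	optic_nerve	right	1.64	0.28	1.43	0.23
nCSF	optic_tract	left	0.249	0.027	0.231	0.039
nCSF	optic_tract	right	0.244	0.060	0.238	0.054
nCSF	chiasm	both	0.338	0.138	0.357	0.071
nCSF	optic_nerve	left	0.177	0.040	0.202	0.074
nCSF	optic_nerve	right	0.222	0.070	0.184	0.067
nGM	optic_tract	left	0.338	0.074	0.529	0.076
nGM	optic_tract	right	0.324	0.108	0.514	0.076
nGM	chiasm	both	0.182	0.090	0.381	0.122
nGM	optic_nerve	left	0.272	0.092	0.372	0.060
nGM	optic_nerve	right	0.256	0.096	0.357	0.061
nWM	optic_tract	left	0.407	0.066	0.233	0.075
nWM	optic_tract	right	0.424	0.126	0.241	0.063
nWM	chiasm	both	0.473	0.117	0.225	0.131
nWM	optic_nerve	left	0.228	0.042	0.127	0.052
nWM	optic_nerve	right	0.268	0.068	0.121	0.046
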