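name	group	phenotype	es_a	s_n	s_p	s_si	s_chl	kp	kt_p	km	kt_m	kr	kt_r	s_s	v_a	temp_fun
Diat-E	diatoms	energy	0.2700	0.210	0.0180	0.6600	0.040	0.350	1.060	0.035	1.080	0.031	1.072	0.0175	0.0	exp
Diat-P	diatoms	phosphorus	0.1875	0.188	0.0113	0.5500	0.025	0.350	1.054	0.045	1.085	0.031	1.072	0.0175	0.0	exp
Green-E	greens	energy	0.2250	0.275	0.0238	0.0018	0.033	0.068	0.000	0.035	1.080	0.031	1.072	0.0175	0.0	lin
Green-N	greens	nitrogen	0.1875	0.175	0.0155	0.0018	0.025	0.068	3.000	0.045	1.085	0.031	1.072	0.0175	0.0	lin
Green-P	greens	phosphorus	0.1875	0.200	0.0129	0.0018	0.025	0.068	3.000	0.045	1.085	0.031	1.072	0.0175	0.0	lin
Aphan-E	Aphanizomenon	energy	0.4500	0.220	0.0125	0.0018	0.033	0.190	1.083	0.035	1.080	0.012	1.072	0.0175	0.0	exp
Aphan-N	Aphanizomenon	nitrogen	0.4000	0.125	0.0125	0.0018	0.025	0.150	1.095	0.045	1.085	0.012	1.072	0.0175	0.0	exp
Aphan-P	Aphanizomenon	phosphorus	0.4000	0.170	0.0088	0.0018	0.025	0.150	1.095	0.045	1.085	0.012	1.072	0.0175	0.0	exp
Micro-E	Microcystis	energy	0.4000	0.225	0.0300	0.0018	0.025	0.056	3.000	0.035	1.080	0.012	1.072	0.0175	0.0	lin
Micro-N	Microcystis	nitrogen	0.2875	0.113	0.0275	0.0018	0.017	0.048	5.000	0.045	1.085	0.012	1.072	0.0175	0.0	lin
Micro-P	Microcystis	phosphorus	0.2875	0.175	0.0225	0.0018	0.017	0.048	5.000	0.045	1.085	0.012	1.072	0.0175	0.0	lin
Oscil-E	Oscillatoria	energy	0.4000	0.225	0.0188	0.0018	0.033	0.045	0.000	0.035	1.080	0.012	1.072	0.0175	0.0	lin
Oscil-N	Oscillatoria	nitrogen	0.2875	0.125	0.0138	0.0018	0.020	0.034	0.000	0.045	1.085	0.012	1.072	0.0175	0.0	lin
Oscil-P	Oscillatoria	phosphorus	0.2875	0.150	0.0113	0.0018	0.020	0.034	0.000	0.045	1.085	0.012	1.072	0.0175	0.0	lin
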