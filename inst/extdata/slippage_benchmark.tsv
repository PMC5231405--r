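label	STAB1	STAB2	STAB3	E188_1	E188_2	E188_3	E188_4	E188_5	E188_6
STAB1	NA	0.229	0.158	0.414	0.349	0.442	0.361	0.344	0.343
STAB2	0.826	NA	0.188	0.496	0.459	0.512	0.334	0.343	0.333
STAB3	1.362	1.917	NA	0.393	0.343	0.414	0.292	0.287	0.277
E188_1	1.168	1.133	1.682	NA	0.275	0.146	0.305	0.301	0.301
E188_2	0.909	1.140	1.224	0.584	NA	0.301	0.351	0.309	0.341
E188_3	1.085	1.110	1.530	0.233	0.459	NA	0.346	0.315	0.313
E188_4	1.548	1.140	2.453	0.893	1.316	1.040	NA	0.175	0.117
E188_5	1.295	0.978	2.096	0.593	0.969	0.716	0.449	NA	0.140
E188_6	1.424	1.058	2.300	0.770	1.182	0.905	0.193	0.306	NA
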