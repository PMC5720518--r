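# reference click-type statistics from a five-site Gulf of Mexico
# monitoring program: per type, the number of five-minute training bins in
# the cluster, peak-frequency mean (CV), the modal ICI, and the mean (CV)
# of per-bin modal ICIs
# training_bins 5000
label	cluster_size	peak_khz_mean	peak_khz_cv	modal_ici	mean_modal_ici	cv_modal_ici
A	91	27.1	0.10	0.155	0.130	0.38
B	205	33.2	0.07	0.125	0.156	0.32
C	74	21.7	0.06	0.165	0.168	0.27
D	231	42.2	0.10	0.035	0.071	0.46
E	1118	32.3	0.11	0.065	0.074	0.33
F	2328	30.3	0.18	0.065	0.073	0.37
G	833	36.5	0.16	0.035	0.079	0.76
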