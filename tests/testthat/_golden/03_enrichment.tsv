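set_id	name	k_overlap	m_set	n_selected	N_universe	p_value	fdr_q	significant
FOCAL_ADHESION_SYN	synthetic focal-adhesion-like pathway	10	12	17	60	1.29344e-05	7.76065e-05	TRUE
DECOY_1	decoy set 1	5	25	17	60	0.9352	1	FALSE
DECOY_2	decoy set 2	3	25	17	60	0.99721	1	FALSE
DECOY_3	decoy set 3	1	15	17	60	0.997151	1	FALSE
DECOY_4	decoy set 4	0	5	17	60	1	1	FALSE
DECOY_5	decoy set 5	3	25	17	60	0.99721	1	FALSE
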