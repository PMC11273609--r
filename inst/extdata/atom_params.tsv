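element	mass_amu	vdw_radius_A	Rmin_A	epsilon_kJ_mol	default_charge_e
H	1.008	1.20	2.40	0.19	0
C	12.011	1.70	4.00	0.30	0
N	14.007	1.55	3.70	0.84	0
O	15.999	1.52	3.40	0.50	0
S	32.060	1.80	4.00	1.88	0
P	30.974	1.80	4.30	2.40	0
FE	55.845	1.40	2.60	0.02	0
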