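# Thermal inactivation constants of native and modified laccases at 60 C
# (EM = Ensifer meliloti L3.8, CU = Cerrena unicolor C-139).
# kd_min_inv is the first-order inactivation rate constant (min^-1),
# t_half_min the published half-life (min), R the published stabilization
# ratio t_half(modified)/t_half(control); NA for the controls.
variant	kd_min_inv	t_half_min	R
EM_control	31.55e-4	219.7	NA
Glc-ver-EM	44.81e-4	154.7	0.7
Glc-EM	53.36e-4	129.9	0.6
Gal-ver-EM	27.45e-4	252.5	1.1
Gal-EM	59.55e-4	116.4	0.5
Cel-ver-EM	39.54e-4	175.3	0.8
Cel-EM	48.10e-4	144.1	0.7
Lac-ver-EM	38.90e-4	178.2	0.8
Lac-EM	70.87e-4	97.8	0.4
GA-ver-EM	45.27e-4	153.1	0.7
GA-EM	62.17e-4	111.5	0.5
CDI-ver-EM	50.30e-4	137.8	0.6
CDI-EM	26.18e-4	264.8	1.2
GA-CDI-ver-EM	7.38e-4	938.7	4.3
GA-CDI-EM	20.70e-4	334.9	1.5
NHSP-ver-EM	110.02e-4	63.0	0.3
NHSP-EM	108.99e-4	63.6	0.3
CA-EM	116.11e-4	59.7	0.3
EGNHS-EM	25.46e-4	272.2	1.2
PS-EM	15.85e-4	437.3	2.0
CU_control	145.31e-4	47.7	NA
CA-CU	3.88e-4	1787.4	37.5
EGNHS-CU	62.39e-4	111.1	2.3
PS-CU	11.54e-4	600.8	12.6
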