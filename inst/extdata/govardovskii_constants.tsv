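# Visual pigment absorbance template constants, transcribed from
# Govardovskii, Fyhrquist, Reuter, Kuzmin & Donner (2000) Vis Neurosci 17:509-528.
# alpha band: S(x) = 1 / (exp(A*(a - x)) + exp(B*(b - x)) + exp(C*(cc - x)) + D),
#   x = lambda_max / lambda, with lambda-max-dependent terms:
#   A1: a  = a0 + a_amp * exp(-(lambda_max - a_mu)^2 / a_denom)
#   A2: a  = a0 + a_amp * exp((lambda_max - a_mu) / a_scale)
#       A  = A0 + A_amp * exp((lambda_max - A_mu) / A_scale)
# beta band: S_beta(lambda) = amp * exp(-((lambda - mu) / bw)^2),
#   mu = mu0 + mu_slope * lambda_max
#   A1: bw = bw0 + bw_slope * lambda_max
#   A2: bw = bw0 + bw_slope * lambda_max + bw_quad * lambda_max^2
chromophore	band	parameter	value
A1	alpha	A	69.7
A1	alpha	B	28
A1	alpha	b	0.922
A1	alpha	C	-14.9
A1	alpha	cc	1.104
A1	alpha	D	0.674
A1	alpha	a0	0.8795
A1	alpha	a_amp	0.0459
A1	alpha	a_mu	300
A1	alpha	a_denom	11940
A1	beta	amp	0.26
A1	beta	mu0	189
A1	beta	mu_slope	0.315
A1	beta	bw0	-40.5
A1	beta	bw_slope	0.195
A2	alpha	A0	62.7
A2	alpha	A_amp	1.834
A2	alpha	A_mu	625
A2	alpha	A_scale	54.2
A2	alpha	B	20.85
A2	alpha	b	0.9101
A2	alpha	C	-10.37
A2	alpha	cc	1.1123
A2	alpha	D	0.5343
A2	alpha	a0	0.875
A2	alpha	a_amp	0.0268
A2	alpha	a_mu	665
A2	alpha	a_scale	40.7
A2	beta	amp	0.37
A2	beta	mu0	216.7
A2	beta	mu_slope	0.287
A2	beta	bw0	317
A2	beta	bw_slope	-1.149
A2	beta	bw_quad	0.00124
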