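outcome	model	neg2ll	df	bic_printed
inattention	full	46686.23	42	47094.16
inattention	no_covariance	46687.96	39	47066.75
inattention	direct_only	46698.83	37	47058.19
inattention	null	46711.79	36	47061.44
hyperactivity	full	46894.51	42	47302.42
hyperactivity	no_covariance	46896.07	39	47274.85
hyperactivity	direct_only	46914.78	37	47274.13
hyperactivity	null	46921.15	36	47270.79
language	full	45695.36	42	46103.38
language	no_covariance	45696.52	39	46075.40
language	direct_only	45697.50	37	46056.95
language	null	45705.78	36	46055.51
motor	full	45484.60	42	45892.50
motor	no_covariance	45484.73	39	45863.49
motor	direct_only	45487.99	37	45847.33
motor	null	45494.10	36	45843.72
rrbi	full	46117.38	42	46525.35
rrbi	no_covariance	46121.59	39	46500.41
rrbi	direct_only	46131.58	37	46490.97
rrbi	null	46134.76	36	46484.45
social_communication	full	46110.86	42	46518.89
social_communication	no_covariance	46114.81	39	46493.69
social_communication	direct_only	46114.86	37	46474.31
social_communication	null	46124.09	36	46473.84
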