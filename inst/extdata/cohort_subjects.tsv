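subject_id	age_years	group	mean_fd_mm
rd01	23	athlete	0.191
rd02	24	athlete	0.059
rd03	24	athlete	0.054
rd04	26	athlete	0.146
rd05	26	athlete	0.118
rd06	27	athlete	0.159
rd07	28	athlete	0.061
rd08	29	athlete	0.062
rd09	30	athlete	0.476
rd10	31	athlete	0.066
rd11	32	athlete	0.095
rd12	32	athlete	0.062
rd13	35	athlete	0.073
rd14	35	athlete	0.072
rd15	36	athlete	0.163
rd16	40	athlete	0.137
rd17	41	athlete	0.076
rd18	41	athlete	0.077
rd19	45	athlete	0.064
ctrl01	19	control	0.069
ctrl02	20	control	0.054
ctrl03	21	control	0.065
ctrl04	21	control	0.062
ctrl05	21	control	0.055
ctrl06	22	control	0.045
ctrl07	22	control	0.109
ctrl08	22	control	0.066
ctrl09	23	control	0.07
ctrl10	25	control	0.062
ctrl11	25	control	0.138
ctrl12	26	control	0.047
ctrl13	29	control	0.065
ctrl14	49	control	0.069
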