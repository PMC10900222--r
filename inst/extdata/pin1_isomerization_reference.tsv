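# Reference free-energy, rate and diffusion measurements for prolyl
# cis-trans isomerization of the FFpSPR substrate peptide, free in solution
# and bound to Pin1 constructs, under modified (alpha < 1) and real
# (V2 = 28 kcal/mol) activation potentials.  Literature-derived inputs for
# the comparative-report module.  Units: free energies kcal/mol, rates 1/s,
# diffusion coefficients deg^2/s.  provenance: extrapolated = obtained via
# the reduced-barrier extrapolation scheme; direct = sampled at the real
# potential.
system	V2	alpha	dG_tc	dG_tc_err	dG_ct	dG_ct_err	dG_cis_trans	dG_cis_trans_err	k	k_err	D_eff	D_eff_err	provenance
FFSPR	7.0	0.25	4.33	0.07	2.93	0.11	1.40	0.09	7.72e7	0.70e7	NA	NA	direct
FFSPR	8.4	0.30	5.28	0.05	3.85	0.10	1.43	0.10	2.55e7	0.07e7	NA	NA	direct
FFSPR	9.8	0.35	6.72	0.05	4.98	0.09	1.74	0.08	5.02e6	0.07e6	NA	NA	direct
FFSPR	28.0	1.00	23.50	0.47	20.39	0.51	3.11	0.45	1.08e-5	0.17e-5	4.50e14	0.72e14	extrapolated
FFpSPR	7.0	0.25	4.02	0.06	2.45	0.10	1.57	0.08	4.15e7	0.12e7	NA	NA	direct
FFpSPR	8.4	0.30	5.25	0.07	3.60	0.10	1.65	0.07	1.75e7	0.03e7	NA	NA	direct
FFpSPR	9.8	0.35	6.55	0.06	4.66	0.10	1.90	0.09	1.23e7	0.04e7	NA	NA	direct
FFpSPR	28.0	1.00	24.47	0.58	21.24	0.52	3.23	0.60	6.29e-7	3.68e-7	1.11e14	0.65e14	extrapolated
FFpSPR-PPIase	9.8	0.35	3.20	0.10	0.62	0.13	2.57	0.11	7.90e6	0.24e6	NA	NA	direct
FFpSPR-PPIase	11.2	0.40	3.88	0.05	1.13	0.07	2.75	0.06	5.13e6	0.08e6	NA	NA	direct
FFpSPR-PPIase	12.6	0.45	5.67	0.13	2.12	0.16	3.55	0.10	1.91e6	0.01e6	NA	NA	direct
FFpSPR-PPIase	28.0	1.00	16.60	0.03	14.16	0.07	2.45	0.07	4.07e-2	2.21e-2	1.66e13	0.90e13	mixed
FFpSPR-Pin1	12.0	0.43	3.13	0.12	0.91	0.15	2.22	0.10	7.45e7	2.50e7	NA	NA	direct
FFpSPR-Pin1	12.6	0.45	4.79	0.03	0.58	0.05	4.21	0.04	1.94e7	0.14e7	NA	NA	direct
FFpSPR-Pin1	14.0	0.50	5.41	0.05	2.85	0.07	2.56	0.05	7.37e6	0.45e6	NA	NA	direct
FFpSPR-Pin1	28.0	1.00	16.08	0.12	13.63	0.16	2.45	0.12	2.30e-1	0.39e-1	4.99e13	0.84e13	mixed
FFpSPR-FFpSPR	9.8	0.35	3.20	0.08	0.20	0.12	3.00	0.09	1.09e7	0.02e7	NA	NA	direct
FFpSPR-FFpSPR	11.2	0.40	4.24	0.09	0.17	0.13	4.07	0.09	6.70e6	0.09e6	NA	NA	direct
FFpSPR-FFpSPR	12.6	0.45	5.52	0.05	0.06	0.08	5.47	0.07	7.79e6	0.10e6	NA	NA	direct
FFpSPR-FFpSPR	28.0	1.00	16.90	0.08	12.60	0.12	4.28	0.10	1.46e-2	1.28e-2	1.00e13	0.88e13	mixed
FFpSPR-pTPP	12.0	0.43	4.34	0.07	1.08	0.10	3.27	0.07	3.97e7	0.54e7	NA	NA	direct
FFpSPR-pTPP	12.6	0.45	3.78	0.07	1.25	0.11	2.53	0.08	5.17e6	0.05e6	NA	NA	direct
FFpSPR-pTPP	14.0	0.50	4.85	0.07	2.36	0.10	2.49	0.08	3.46e6	0.03e6	NA	NA	direct
FFpSPR-pTPP	28.0	1.00	15.46	0.04	13.07	0.06	2.39	0.05	1.05e-1	0.24e-1	6.51e12	1.47e12	mixed
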