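chrT	6000	6500	pk_body	0	.
chrT	3001	4001	pk_1bp	0	.
chrT	3000	4000	pk_touch	0	.
chrT	22999	23999	pk_999	0	.
chrT	23000	24000	pk_1000	0	.
chrT	23001	24001	pk_1001	0	.
chrT	30500	30900	pk_other	0	.
chrT	40000	41000	pk_far	0	.
chrT	50010	50021	pk_odd	0	.
chrT	0	300	pk_start	0	.
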