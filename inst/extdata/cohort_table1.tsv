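variable	type	mean_control	sd_control	n_control	mean_cpa	sd_cpa	n_cpa	control_yes	control_no	cpa_yes	cpa_no
age_at_blood_draw	summary	25.4	2.71	12	25.8	2.87	8	NA	NA	NA	NA
familial_adversity_score	summary	0.34	0.29	12	0.51	0.41	7	NA	NA	NA	NA
psychiatric_record_21y	count	NA	NA	NA	NA	NA	NA	6	4	3	4
criminal_record_21y	count	NA	NA	NA	NA	NA	NA	2	10	6	2
self_reported_violence_21y	count	NA	NA	NA	NA	NA	NA	1	9	4	3
attention_deficit_score_6_15y	summary	3.23	2.18	12	4.00	1.89	8	NA	NA	NA	NA
hyperactivity_trajectories_6_15y	count	NA	NA	NA	NA	NA	NA	3	9	4	4
opposition_trajectories_6_15y	count	NA	NA	NA	NA	NA	NA	0	12	6	2
anxiety_trajectories_6_15y	count	NA	NA	NA	NA	NA	NA	1	11	1	7
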