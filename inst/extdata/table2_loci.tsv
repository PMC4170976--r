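locus	species	status	n	A	size_range	ho	he	hwe_deviates
Ant20	P_clavata	amplified	10	1	137	0	0	no
Ant20	S_pentadentata	amplified	10	3	171-177	0.3	0.54	no
Ant20	D_molestus	amplified	10	1	150	0	0	no
Ant20	L_nearcticus	amplified	10	1	74	0	0	no
Ant20	E_ruidum	amplified	10	1	140	0	0	no
Ant20	S_invicta	amplified	10	1	153	0	0	no
Ant575	P_clavata	amplified	10	4	370-379	0.9	0.63	no
Ant575	S_pentadentata	amplified	10	11	334-375	0.4	0.96	yes
Ant575	D_molestus	amplified	10	2	230-250	0.2	0.19	no
Ant575	L_nearcticus	amplified	10	4	209-234	0.3	0.37	no
Ant575	E_ruidum	amplified	10	1	248	0	0	no
Ant575	S_invicta	amplified	10	3	218-239	0.7	0.63	no
Ant859	P_clavata	amplified	10	5	184-206	0.7	0.77	no
Ant859	S_pentadentata	amplified	10	3	180-184	0.3	0.54	no
Ant859	D_molestus	amplified	10	2	197-199	0.2	0.19	no
Ant859	L_nearcticus	amplified	9	11	175-204	1	0.94	no
Ant859	E_ruidum	amplified	10	1	158	0	0	no
Ant859	S_invicta	amplified	10	1	191	0	0	no
Ant1343	P_clavata	amplified	10	4	229-235	0.6	0.53	no
Ant1343	S_pentadentata	amplified	10	1	186	0	0	no
Ant1343	D_molestus	amplified	10	4	263-269	0.6	0.76	no
Ant1343	L_nearcticus	amplified	10	3	206-211	0.4	0.58	no
Ant1343	E_ruidum	amplified	10	1	221	0	0	no
Ant1343	S_invicta	amplified	10	4	252-272	0.9	0.71	no
Ant1368	P_clavata	amplified	10	1	251	0	0	no
Ant1368	S_pentadentata	amplified	7	6	266-313	0.14	0.93	yes
Ant1368	D_molestus	amplified	10	8	299-322	0.9	0.85	no
Ant1368	L_nearcticus	amplified	10	5	278-309	0.6	0.62	no
Ant1368	E_ruidum	amplified	10	1	269	0	0	no
Ant1368	S_invicta	amplified	10	1	280	0	0	no
Ant2341	P_clavata	no_amplification
Ant2341	S_pentadentata	amplified	10	5	345-359	0.7	0.76	no
Ant2341	D_molestus	amplified	10	4	256-267	0.2	0.55	no
Ant2341	L_nearcticus	amplified	10	2	212-215	0.4	0.51	no
Ant2341	E_ruidum	amplified	10	1	184	0	0	no
Ant2341	S_invicta	amplified	10	2	245-251	0.3	0.27	no
Ant2794	P_clavata	amplified	10	3	241-251	0.5	0.42	no
Ant2794	S_pentadentata	amplified	9	9	280-336	0.67	0.90	no
Ant2794	D_molestus	amplified	10	5	246-270	0.4	0.77	no
Ant2794	L_nearcticus	amplified	10	10	240-268	1	0.89	no
Ant2794	E_ruidum	amplified	10	1	218	0	0	no
Ant2794	S_invicta	amplified	9	1	258	0	0	no
Ant2936	P_clavata	no_amplification
Ant2936	S_pentadentata	no_amplification
Ant2936	D_molestus	amplified	10	7	314-336	0.3	0.92	yes
Ant2936	L_nearcticus	amplified	10	9	352-390	0.4	0.9	no
Ant2936	E_ruidum	no_amplification
Ant2936	S_invicta	amplified	10	5	349-365	0.1	0.81	yes
Ant3648	P_clavata	amplified	9	1	337	0	0	no
Ant3648	S_pentadentata	amplified	10	10	368-410	0.5	0.94	yes
Ant3648	D_molestus	amplified	10	7	376-421	0.5	0.83	no
Ant3648	L_nearcticus	amplified	10	3	332-343	0.6	0.57	no
Ant3648	E_ruidum	amplified	10	4	393-401	0.3	0.67	no
Ant3648	S_invicta	amplified	10	1	337	0	0	no
Ant3653	P_clavata	amplified	10	1	273	0	0	no
Ant3653	S_pentadentata	amplified	10	9	238-254	0.8	0.85	no
Ant3653	D_molestus	amplified	10	3	255-259	0.6	0.62	no
Ant3653	L_nearcticus	amplified	10	9	261-319	0.4	0.9	yes
Ant3653	E_ruidum	amplified	10	4	357-363	0.4	0.74	no
Ant3653	S_invicta	amplified	10	2	254-256	0.4	0.33	no
Ant3993	P_clavata	amplified	8	7	368-387	0.88	0.88	no
Ant3993	S_pentadentata	amplified	10	5	368-379	0.2	0.81	yes
Ant3993	D_molestus	amplified	10	2	311-317	0.5	0.48	no
Ant3993	L_nearcticus	amplified	10	7	379-419	0.7	0.77	no
Ant3993	E_ruidum	amplified	8	1	454	0	0	no
Ant3993	S_invicta	amplified	10	3	375-363	0.7	0.47	no
Ant4155	P_clavata	amplified	10	1	162	0	0	no
Ant4155	S_pentadentata	amplified	8	3	206-211	0.38	0.64	no
Ant4155	D_molestus	amplified	10	4	176-195	0.8	0.61	no
Ant4155	L_nearcticus	amplified	10	1	170	0	0	no
Ant4155	E_ruidum	amplified	10	1	158	0	0	no
Ant4155	S_invicta	amplified	10	2	200-203	0.2	0.19	no
Ant5035	P_clavata	amplified	10	2	340-342	0.4	0.33	no
Ant5035	S_pentadentata	amplified	10	9	412-442	0.3	0.94	yes
Ant5035	D_molestus	amplified	10	6	365-384	0.8	0.77	no
Ant5035	L_nearcticus	amplified	10	8	284-341	0.8	0.9	no
Ant5035	E_ruidum	amplified	10	1	331	0	0	no
Ant5035	S_invicta	amplified	10	1	311	0	0	no
Ant7249	P_clavata	amplified	10	1	425	0	0	no
Ant7249	S_pentadentata	amplified	10	7	320-359	0.4	0.86	yes
Ant7249	D_molestus	amplified	10	6	369-398	0.5	0.68	no
Ant7249	L_nearcticus	amplified	10	5	345-368	0.6	0.74	no
Ant7249	E_ruidum	amplified	10	1	325	0	0	no
Ant7249	S_invicta	amplified	10	1	358	0	0	no
Ant7680	P_clavata	amplified	10	1	306	0	0	no
Ant7680	S_pentadentata	amplified	9	11	332-386	0.56	0.97	yes
Ant7680	D_molestus	amplified	10	6	310-328	0.6	0.74	no
Ant7680	L_nearcticus	amplified	10	1	257	0	0	no
Ant7680	E_ruidum	amplified	10	1	219	0	0	no
Ant7680	S_invicta	amplified	10	1	264	0	0	no
Ant8424	P_clavata	amplified	10	2	262-265	0.2	0.19	no
Ant8424	S_pentadentata	amplified	10	8	894-318	0.5	0.82	no
Ant8424	D_molestus	amplified	10	3	232-238	0.5	0.48	no
Ant8424	L_nearcticus	amplified	10	4	193-240	0.4	0.36	no
Ant8424	E_ruidum	amplified	10	2	266-275	0.4	0.44	no
Ant8424	S_invicta	amplified	10	3	235-259	0.4	0.35	no
Ant8498	P_clavata	amplified	10	2	214-218	0.4	0.51	no
Ant8498	S_pentadentata	amplified	10	1	181	0	0	no
Ant8498	D_molestus	amplified	10	1	147	0	0	no
Ant8498	L_nearcticus	amplified	10	1	145	0	0	no
Ant8498	E_ruidum	amplified	10	1	172	0	0	no
Ant8498	S_invicta	amplified	10	1	201	0	0	no
Ant9181	P_clavata	amplified	10	1	280	0	0	no
Ant9181	S_pentadentata	no_amplification
Ant9181	D_molestus	amplified	10	4	355-371	0.3	0.62	no
Ant9181	L_nearcticus	amplified	10	1	271	0	0	no
Ant9181	E_ruidum	no_amplification
Ant9181	S_invicta	no_amplification
Ant9218	P_clavata	amplified	10	1	335	0	0	no
Ant9218	S_pentadentata	amplified	5	6	500-564	0.6	0.93	no
Ant9218	D_molestus	amplified	10	4	311-322	0.7	0.74	no
Ant9218	L_nearcticus	amplified	10	5	336-343	0.4	0.44	no
Ant9218	E_ruidum	amplified	10	1	383	0	0	no
Ant9218	S_invicta	amplified	10	1	360	0	0	no
Ant10878	P_clavata	amplified	10	1	302	0	0	no
Ant10878	S_pentadentata	amplified	10	7	358-377	0.6	0.88	no
Ant10878	D_molestus	amplified	10	3	292-298	0.6	0.51	no
Ant10878	L_nearcticus	amplified	10	8	280-321	0.8	0.86	no
Ant10878	E_ruidum	amplified	10	2	283-285	0.1	0.1	no
Ant10878	S_invicta	amplified	10	1	320	0	0	no
Ant11315	P_clavata	amplified	10	1	358	0	0	no
Ant11315	S_pentadentata	amplified	10	1	380	0	0	no
Ant11315	D_molestus	amplified	10	1	317	0	0	no
Ant11315	L_nearcticus	amplified	10	1	355	0	0	no
Ant11315	E_ruidum	amplified	10	1	322	0	0	no
Ant11315	S_invicta	amplified	10	1	343	0	0	no
Ant11400	P_clavata	amplified	10	1	258	0	0	no
Ant11400	S_pentadentata	amplified	10	9	259-336	0.7	0.85	no
Ant11400	D_molestus	amplified	10	2	234-238	0.3	0.53	no
Ant11400	L_nearcticus	amplified	9	1	242	0	0	no
Ant11400	E_ruidum	amplified	10	1	294	0	0	no
Ant11400	S_invicta	amplified	10	1	251	0	0	no
Ant11893	P_clavata	amplified	10	9	375-392	1	0.89	no
Ant11893	S_pentadentata	amplified	10	5	377-412	0.2	0.82	yes
Ant11893	D_molestus	amplified	10	4	390-398	0.5	0.73	no
Ant11893	L_nearcticus	amplified	10	1	336	0	0	no
Ant11893	E_ruidum	amplified	10	1	321	0	0	no
Ant11893	S_invicta	amplified	10	4	343-358	0.6	0.66	no
Ant12220	P_clavata	amplified	10	1	378	0	0	no
Ant12220	S_pentadentata	no_amplification
Ant12220	D_molestus	amplified	10	3	274-280	0.3	0.28	no
Ant12220	L_nearcticus	amplified	10	1	226	0	0	no
Ant12220	E_ruidum	amplified	10	2	306-360	0.3	0.4	no
Ant12220	S_invicta	amplified	10	1	327	0	0	no
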