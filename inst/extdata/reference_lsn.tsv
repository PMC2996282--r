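index	MTNR1B_rs10830963	HHEX_rs7923837	CDKAL1_rs7754840	TCF7L2_rs7903146	WFS1_rs10010131	KCNQ1_rs151290
homa_b	345	4222	34337	2938	2923	42551
insulin_30	196	587	779	4127	2234	852
c_peptide_30	241	536	2289	4800	1164	657
igi1	201	483	1914	2376	1537	1046
igi2	164	527	894	3134	2001	797
di_oral	288	568	1715	3285	2250	1127
cir	164	447	1487	2098	1824	1075
first_phase	208	468	936	4951	1976	981
auc_ins_0_30	153	456	810	2808	1855	803
auc_ins_0_120	478	356	4465	1361	5549	1023
auc_cp_0_30	180	500	2993	2580	1112	706
auc_cp_0_120	453	338	8127	1109	1276	677
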