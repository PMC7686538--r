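name	chrom	start	end	n_snvs
MT-ND3	MT	10059	10404	77
MT-ATP6	MT	8527	9207	226
MT-ATP8	MT	8366	8572	73
MT-CO1	MT	5904	7445	319
MT-CO2	MT	7586	8269	152
MT-CO3	MT	9207	9990	182
MT-CYB	MT	14747	15887	326
MT-ND1	MT	3307	4262	218
MT-ND2	MT	4470	5511	236
MT-ND4	MT	10760	12137	291
MT-ND5	MT	12337	14148	408
MT-ND6	MT	14149	14673	128
MT-RNR1	MT	648	1601	118
ADRA1A	8	26738113	26870994	7311
ADRB3	8	37962990	37966599	203
CIDEA	18	12254361	12277595	1445
CREB1	2	207529943	207605988	4353
DIO2	14	80197526	80231057	10223
FTO	16	53703963	54121941	23729
HOXC4	12	54016888	54056030	1801
HOXA1	7	27092993	27096000	149
LIPE	19	42401512	42427421	1485
LEP	7	128241201	128257629	863
LEPR	1	65420652	65641559	11705
NRF1	7	129611720	129757082	6949
NRIP1	21	14961235	15065903	753
PLIN1	15	89664365	89679367	865
PLIN2	9	19108391	19127606	2751
PLIN3	19	4838341	4867667	2141
PLIN5	19	4522531	4535224	999
PPARG	3	12287368	12434344	7539
PPARGC1A	4	23792021	24472905	5581
PPARGC1B	5	149730302	149857861	7307
PRDM16	1	3069203	3438621	28237
PRKAR1A	17	68413623	68551316	1869
PRKAR2A	3	48744601	48847874	4663
PRKAR1B	7	549185	727676	14603
PRKAR2B	7	107044705	107161811	6691
UCP1	4	140555770	140568961	369
UCP2	11	73974671	73983202	517
UCP3	11	74000277	74009237	587
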