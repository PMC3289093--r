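gene	rpkm_white	rpkm_green	printed_ratio	table
PP038070	0.3	7	23.3333	2
PP043130	0.3	4.2	14	2
PP013262	0.7	3.5	5	2
PP011276	1.1	4.3	3.90909	2
PP088927	5.4	18.9	3.5	2
PP019996	0.2	36.9	184.5	2
PP013404	1.1	100.8	91.6364	2
PP042072	0.2	12.1	60.5	2
PP032956	2.5	140.7	56.28	2
PP036244	0.5	15.5	31	2
PP026927	1	26.9	26.9	2
PP032648	0.5	12	24	2
PP034454	1.2	25.7	21.4167	2
PP014055	4.5	90.2	20.0444	2
PP022096	1.8	34.9	19.3889	2
PP016518	5.2	80.2	15.4231	2
PP036291	5.6	85.6	15.2857	2
PP002791	0.7	10.4	14.8571	2
PP060891	0	13.8	13.8	2
PP032891	0.7	9.4	13.4286	2
PP033574	1.4	18.1	12.9286	2
PP043522	2.1	25.6	12.1905	2
PP004292	6.9	83.9	12.1594	2
PP041756	1.1	13.3	12.0909	2
PP004529	21.5	259.4	12.0651	2
PP003367	14.8	176.1	11.8986	2
PP019899	28.5	328.4	11.5228	2
PP020291	40.5	445.8	11.0074	2
PP055138	0.7	7.6	10.8571	2
PP005460	2.1	21.5	10.2381	2
PP020373	0	9.9	9.9	2
PP021872	12.4	115	9.27419	2
PP034445	0.9	8.3	9.22222	2
PP003971	13.1	117.1	8.93893	2
PP034046	1.1	9.2	8.36364	2
PP033656	4	31.3	7.825	2
PP029126	6	46.1	7.68333	2
PP005284	6.7	47.7	7.1194	2
PP021031	36.8	258.7	7.02989	2
PP016372	2.4	16.7	6.95833	2
PP022981	6.9	47	6.81159	2
PP021682	14.1	91.5	6.48936	2
PP003968	50.6	320	6.32411	2
PP020586	22.7	135.7	5.97797	2
PP005425	5.4	26.2	4.85185	2
PP010147	48.6	226.7	4.66461	2
PP003504	66.3	305.1	4.60181	2
PP004840	40.6	181.7	4.47537	2
PP020865	14.6	61.6	4.21918	2
PP032222	8.6	34.2	3.97674	2
PP021166	104.1	391.8	3.76369	2
PP005062	24.4	90.1	3.69262	2
PP033260	4.3	15.8	3.67442	2
PP032950	102.9	376.3	3.65695	2
PP022979	10	33	3.3	2
PP001298	3.7	12	3.24324	2
PP021716	24.4	78.8	3.22951	2
PP003549	24.1	74.3	3.08299	2
PP008642	0.2	25.8	129	2
PP000591	0.5	54.9	109.8	2
PP006879	0.1	4.7	47	2
PP004388	1.1	45.3	41.1818	2
PP016988	0.2	4.9	24.5	2
PP018045	7.8	174.6	22.3846	2
PP036218	0.3	5	16.6667	2
PP032734	1.1	17.4	15.8182	2
PP020420	14.5	221.7	15.2897	2
PP018042	0	14.7	14.7	2
PP004848	3.4	49.6	14.5882	2
PP014192	7.3	103.1	14.1233	2
PP021663	4.9	63.5	12.9592	2
PP069357	0.7	8.2	11.7143	2
PP005143	6.3	68.6	10.8889	2
PP016409	7.1	60.7	8.5493	2
PP033894	5.6	44.7	7.98214	2
PP014928	10.7	84	7.85047	2
PP017397	10.6	76.7	7.23585	2
PP060944	0	7.1	7.1	2
PP017005	0	6.6	6.6	2
PP021626	0	6.5	6.5	2
PP000042	7.8	48.3	6.19231	2
PP022192	25.2	130.2	5.16667	2
PP032949	6.7	33.7	5.02985	2
PP032493	5.2	25.1	4.82692	2
PP033323	21.5	100.9	4.69302	2
PP033241	6	27.1	4.51667	2
PP033302	7.4	32.5	4.39189	2
PP005186	48.6	205.7	4.23251	2
PP016053	22.9	96.6	4.21834	2
PP022547	5.8	23.8	4.10345	2
PP012172	7.3	29.7	4.06849	2
PP000003	17	68.8	4.04706	2
PP033216	12.2	47.9	3.92623	2
PP041363	2	7.7	3.85	2
PP012010	26.9	95.3	3.54275	2
PP033278	11.6	40.2	3.46552	2
PP033227	10.1	33.6	3.32673	2
PP005055	24	76.9	3.20417	2
PP039593	2.1	6.5	3.09524	2
PP013176	7	21.5	3.07143	2
Toc159	0	23.1	23.1	1
ACP	0	18.7	18.7	1
FtsH8	0	12.8	12.8	1
LHCB1.5	50.6	320	6.32	1
G4	7.8	45.5	5.83	1
FAR1	2	8.2	4.1	1
CRY2	4.4	18.6	4.23	1
HY5	0	7.1	7.1	1
PHOT2	2	6.5	3.25	1
LHCB5	24.4	90.1	3.69	1
GUN5	3.6	14.5	4.03	1
CIP1	14.7	4.1	0.28	1
LSH7	9.1	1.8	0.2	1
HSP70-1	59.2	0.5	0.01	1
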