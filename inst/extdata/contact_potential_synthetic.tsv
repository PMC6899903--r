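	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-0.1296	0.324	0.252	0.252	-0.18	0.252	0.252	0.0288	0.2304	-0.324	-0.2736	0.2808	-0.1368	-0.2016	0.1152	0.0576	0.0504	0.0648	0.0936	-0.3024
R	0.324	-0.81	-0.63	-0.63	0.45	-0.63	-0.63	-0.072	-0.576	0.81	0.684	-0.702	0.342	0.504	-0.288	-0.144	-0.126	-0.162	-0.234	0.756
N	0.252	-0.63	-0.49	-0.49	0.35	-0.49	-0.49	-0.056	-0.448	0.63	0.532	-0.546	0.266	0.392	-0.224	-0.112	-0.098	-0.126	-0.182	0.588
D	0.252	-0.63	-0.49	-0.49	0.35	-0.49	-0.49	-0.056	-0.448	0.63	0.532	-0.546	0.266	0.392	-0.224	-0.112	-0.098	-0.126	-0.182	0.588
C	-0.18	0.45	0.35	0.35	-0.25	0.35	0.35	0.04	0.32	-0.45	-0.38	0.39	-0.19	-0.28	0.16	0.08	0.07	0.09	0.13	-0.42
Q	0.252	-0.63	-0.49	-0.49	0.35	-0.49	-0.49	-0.056	-0.448	0.63	0.532	-0.546	0.266	0.392	-0.224	-0.112	-0.098	-0.126	-0.182	0.588
E	0.252	-0.63	-0.49	-0.49	0.35	-0.49	-0.49	-0.056	-0.448	0.63	0.532	-0.546	0.266	0.392	-0.224	-0.112	-0.098	-0.126	-0.182	0.588
G	0.0288	-0.072	-0.056	-0.056	0.04	-0.056	-0.056	-0.0064	-0.0512	0.072	0.0608	-0.0624	0.0304	0.0448	-0.0256	-0.0128	-0.0112	-0.0144	-0.0208	0.0672
H	0.2304	-0.576	-0.448	-0.448	0.32	-0.448	-0.448	-0.0512	-0.4096	0.576	0.4864	-0.4992	0.2432	0.3584	-0.2048	-0.1024	-0.0896	-0.1152	-0.1664	0.5376
I	-0.324	0.81	0.63	0.63	-0.45	0.63	0.63	0.072	0.576	-0.81	-0.684	0.702	-0.342	-0.504	0.288	0.144	0.126	0.162	0.234	-0.756
L	-0.2736	0.684	0.532	0.532	-0.38	0.532	0.532	0.0608	0.4864	-0.684	-0.5776	0.5928	-0.2888	-0.4256	0.2432	0.1216	0.1064	0.1368	0.1976	-0.6384
K	0.2808	-0.702	-0.546	-0.546	0.39	-0.546	-0.546	-0.0624	-0.4992	0.702	0.5928	-0.6084	0.2964	0.4368	-0.2496	-0.1248	-0.1092	-0.1404	-0.2028	0.6552
M	-0.1368	0.342	0.266	0.266	-0.19	0.266	0.266	0.0304	0.2432	-0.342	-0.2888	0.2964	-0.1444	-0.2128	0.1216	0.0608	0.0532	0.0684	0.0988	-0.3192
F	-0.2016	0.504	0.392	0.392	-0.28	0.392	0.392	0.0448	0.3584	-0.504	-0.4256	0.4368	-0.2128	-0.3136	0.1792	0.0896	0.0784	0.1008	0.1456	-0.4704
P	0.1152	-0.288	-0.224	-0.224	0.16	-0.224	-0.224	-0.0256	-0.2048	0.288	0.2432	-0.2496	0.1216	0.1792	-0.1024	-0.0512	-0.0448	-0.0576	-0.0832	0.2688
S	0.0576	-0.144	-0.112	-0.112	0.08	-0.112	-0.112	-0.0128	-0.1024	0.144	0.1216	-0.1248	0.0608	0.0896	-0.0512	-0.0256	-0.0224	-0.0288	-0.0416	0.1344
T	0.0504	-0.126	-0.098	-0.098	0.07	-0.098	-0.098	-0.0112	-0.0896	0.126	0.1064	-0.1092	0.0532	0.0784	-0.0448	-0.0224	-0.0196	-0.0252	-0.0364	0.1176
W	0.0648	-0.162	-0.126	-0.126	0.09	-0.126	-0.126	-0.0144	-0.1152	0.162	0.1368	-0.1404	0.0684	0.1008	-0.0576	-0.0288	-0.0252	-0.0324	-0.0468	0.1512
Y	0.0936	-0.234	-0.182	-0.182	0.13	-0.182	-0.182	-0.0208	-0.1664	0.234	0.1976	-0.2028	0.0988	0.1456	-0.0832	-0.0416	-0.0364	-0.0468	-0.0676	0.2184
V	-0.3024	0.756	0.588	0.588	-0.42	0.588	0.588	0.0672	0.5376	-0.756	-0.6384	0.6552	-0.3192	-0.4704	0.2688	0.1344	0.1176	0.1512	0.2184	-0.7056
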