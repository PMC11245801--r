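#genome_length=17386 circular=true
cox1	F	1	1554	PCG	ATG	TAG
trnR-cga	F	1560	1625	tRNA	-	-
nad4l	F	<1626	1922	PCG	ATT	TAA
cox2	F	1923	2610	PCG	ATG	T
trnK-aag	F	2611	2675	tRNA	-	-
atp8	F	2677	2844	PCG	ATG	TAA
atp6	F	2838	3521	PCG	ATG	TAA
cox3	F	3525	4307	PCG	ATG	TAA
trnS2-tca	R	4306	4371	tRNA	-	-
nad3	F	4394	4738	PCG	ATG	TAA
nad4	F	4743	6102	PCG	ATG	T
trnH-cac	F	6103	6176	tRNA	-	-
trnS1-agc	F	6178	6244	tRNA	-	-
nad5	F	6246	8078	PCG	ATG	TAA
nad6	R	8101	8589	PCG	ATG	TAA
cytb	F	8598	9741	PCG	ATG	T
trnF-ttc	F	9742	9811	tRNA	-	-
rrnS	F	9812	10643	rRNA	-	-
trnE-gaa	F	10644	10711	tRNA	-	-
trnA-gca	R	11594	11661	tRNA	-	-
trnW-tga	F	11668	11736	tRNA	-	-
trnM-atg	F	11760	11828	tRNA	-	-
trnG-gga	F	11842	11907	tRNA	-	-
trnP-cca	F	11971	12038	tRNA	-	-
trnQ-caa	R	12035	12104	tRNA	-	-
trnN-aac	F	12106	12172	tRNA	-	-
trnL1-cta	F	12173	12244	tRNA	-	-
trnC-tgc	F	12252	12316	tRNA	-	-
trnV-gta	R	12317	12386	tRNA	-	-
trnD-gac	R	12392	12458	tRNA	-	-
trnY-tac	F	12459	12526	tRNA	-	-
trnL2-tta	F	12543	12614	tRNA	-	-
nad1	F	12618	13589	PCG	ATG	TAA
trnI-atc	F	13601	13668	tRNA	-	-
nad2	F	13669	14709	PCG	ATG	TAA
trnT-aca	F	14712	14781	tRNA	-	-
rrnL	F	15935	17385	rRNA	-	-
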