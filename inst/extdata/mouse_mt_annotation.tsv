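#genome_length=16299
#genetic_code=2
name	ftype	start	end	strand	frame
tRNA-Phe	tRNA	1	68	+	NA
mt-Rnr1	rRNA	70	1024	+	NA
tRNA-Val	tRNA	1025	1093	+	NA
mt-Rnr2	rRNA	1094	2675	+	NA
tRNA-Leu1	tRNA	2676	2750	+	NA
mt-Nd1	protein_coding	2751	3707	+	0
tRNA-Ile	tRNA	3708	3776	+	NA
tRNA-Gln	tRNA	3777	3845	-	NA
tRNA-Met	tRNA	3846	3913	+	NA
mt-Nd2	protein_coding	3914	4951	+	0
tRNA-Trp	tRNA	4952	5018	+	NA
tRNA-Ala	tRNA	5019	5087	-	NA
tRNA-Asn	tRNA	5090	5160	-	NA
tRNA-Cys	tRNA	5193	5258	-	NA
tRNA-Tyr	tRNA	5259	5327	-	NA
mt-Co1	protein_coding	5328	6872	+	0
tRNA-Ser2	tRNA	6873	6941	-	NA
tRNA-Asp	tRNA	6942	7011	+	NA
mt-Co2	protein_coding	7013	7696	+	0
tRNA-Lys	tRNA	7700	7764	+	NA
mt-Atp8	protein_coding	7766	7969	+	0
mt-Atp6	protein_coding	7927	8607	+	0
mt-Co3	protein_coding	8607	9390	+	0
tRNA-Gly	tRNA	9391	9458	+	NA
mt-Nd3	protein_coding	9459	9806	+	0
tRNA-Arg	tRNA	9808	9875	+	NA
mt-Nd4l	protein_coding	9877	10173	+	0
mt-Nd4	protein_coding	10167	11544	+	0
tRNA-His	tRNA	11546	11613	+	NA
tRNA-Ser1	tRNA	11614	11672	+	NA
tRNA-Leu2	tRNA	11673	11742	+	NA
mt-Nd5	protein_coding	11742	13565	+	0
mt-Nd6	protein_coding	13552	14070	-	0
tRNA-Glu	tRNA	14071	14139	-	NA
mt-Cytb	protein_coding	14145	15287	+	0
tRNA-Thr	tRNA	15289	15355	+	NA
tRNA-Pro	tRNA	15356	15422	-	NA
D-loop	D_loop	15443	16299	+	NA
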