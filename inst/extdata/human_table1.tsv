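gene_id	species	scaffold	start	end	strand	group	family
ERP27	H_sapiens	12	14914035	14939082	-	PDIA8	PDI
ARHGDIB	H_sapiens	12	14942017	14961722	-	RhoGDIb	RhoGDI
ARHGDIG	H_sapiens	16	268727	283010	+	RhoGDIg	RhoGDI
PDIA2	H_sapiens	16	283152	287215	+	PDIA2	PDI
P4HB	H_sapiens	17	81843159	81860694	-	PDIA1	PDI
ARHGDIA	H_sapiens	17	81867721	81871406	-	RhoGDIa	RhoGDI
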