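id_cp_interaction	interacting_pair	partner_a	partner_b	receptor_a	receptor_b	EmbA|EmbA	EmbA|EmbB	EmbA|EmbC	EmbA|ExE	EmbA|Blood	EmbB|EmbA	EmbB|EmbB	EmbB|EmbC	EmbB|ExE	EmbB|Blood	EmbC|EmbA	EmbC|EmbB	EmbC|EmbC	EmbC|ExE	EmbC|Blood	ExE|EmbA	ExE|EmbB	ExE|EmbC	ExE|ExE	ExE|Blood	Blood|EmbA	Blood|EmbB	Blood|EmbC	Blood|ExE	Blood|Blood
CPI-001	Bmp4:Bmpr1a	sP_Bmp4	sP_Bmpr1a	False	True																2.34	1.08	1.56		1.74					
CPI-002	Lefty1:Tdgf1	sP_Lefty1	sP_Tdgf1	False	True																1.59	1.29	2.47		1.30					
CPI-003	Wnt3:Fzd5	sP_Wnt3	sP_Fzd5	False	True																3.03	1.32	2.27		3.37					
CPI-004	Fgf8:Fgfr1	sP_Fgf8	sP_Fgfr1	False	True																0.77	1.21	1.28		1.74					
CPI-005	Nodal:Acvr2a	sP_Nodal	sP_Acvr2a	False	True																1.20	0.47	0.51		2.29					
CPI-006	Kitl:Kit	sP_Kitl	sP_Kit	False	True																1.19	0.66	1.26		2.19					
CPI-007	Vegfa:Kdr	sP_Vegfa	sP_Kdr	False	True					2.88					1.14					1.22					0.67					
CPI-008	Dll1:Notch1	sP_Dll1	sP_Notch1	False	True					1.62					1.04					1.62					1.79					
CPI-009	Jag1:Notch2	sP_Jag1	sP_Notch2	False	True					2.04					1.06					1.65					0.68					
CPI-010	Cxcl12:Cxcr4	sP_Cxcl12	sP_Cxcr4	False	True					0.99					0.96					0.51					1.37					
CPI-011	Angpt1:Tek	sP_Angpt1	sP_Tek	False	True					1.47					1.17					1.83					1.01					
CPI-012	Epo:Epor	sP_Epo	sP_Epor	False	True					0.78					1.61					0.98					2.41					
CPI-013	Cdh1:Cdh1	sP_Cdh1	sP_Cdh1	False	False		1.14				1.75																			
CPI-014	Efna1:Epha4	sP_Efna1	sP_Epha4	False	True		1.54				0.99																			
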