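Astrocyte_component_synthetic_1	synthetic astrocyte component list	GLUL	SLC1A2	GFAP	NFIB	SLC1A3	AGT	PPP1R3C	MLC1	SOX9	GJA1	BMPR1B	NFIA	SLC4A4	CLU	GPC5	AQP4	ASTSYN111	ASTSYN003	ASTSYN041	ASTSYN089	ASTSYN027	ASTSYN036	ASTSYN101	ASTSYN095	ASTSYN109	ASTSYN005	ASTSYN084	ASTSYN034	ASTSYN092	ASTSYN104	ASTSYN119	ASTSYN058	ASTSYN097	ASTSYN042	ASTSYN024	ASTSYN030	ASTSYN043	ASTSYN015	ASTSYN022	ASTSYN105	ASTSYN008	ASTSYN115	ASTSYN068	ASTSYN086	ASTSYN018	ASTSYN069
Astrocyte_component_synthetic_2	synthetic astrocyte component list	SLC1A3	AQP4	AGT	S100B	GLUL	RANBP3L	ALDH1L1	ATP1A2	SLC4A4	PPP1R3C	GPC5	BMPR1B	SLC1A2	FGFR3	GJA1	APOE	ASTSYN058	ASTSYN010	ASTSYN040	ASTSYN005	ASTSYN033	ASTSYN049	ASTSYN103	ASTSYN100	ASTSYN109	ASTSYN106	ASTSYN073	ASTSYN029	ASTSYN076	ASTSYN084	ASTSYN009	ASTSYN035	ASTSYN093	ASTSYN016	ASTSYN101	ASTSYN092	ASTSYN069	ASTSYN102	ASTSYN002	ASTSYN082	ASTSYN024	ASTSYN018	ASTSYN113	ASTSYN055	ASTSYN118	ASTSYN021
Astrocyte_component_synthetic_3	synthetic astrocyte component list	SLC1A3	PPP1R3C	GJA1	NFIB	AGT	APOE	FGFR3	GLUL	VIM	NFIA	MLC1	SLC1A2	CD44	CLU	GPC5	SOX9	ASTSYN029	ASTSYN055	ASTSYN038	ASTSYN001	ASTSYN013	ASTSYN078	ASTSYN005	ASTSYN073	ASTSYN119	ASTSYN016	ASTSYN090	ASTSYN043	ASTSYN042	ASTSYN108	ASTSYN097	ASTSYN057	ASTSYN120	ASTSYN025	ASTSYN063	ASTSYN032	ASTSYN081	ASTSYN014	ASTSYN006	ASTSYN047	ASTSYN109	ASTSYN062	ASTSYN037	ASTSYN080	ASTSYN031	ASTSYN034
Astrocyte_component_synthetic_4	synthetic astrocyte component list	ALDH1L1	RANBP3L	PPP1R3C	SLC4A4	BMPR1B	MLC1	AQP4	NFIB	GJA1	VIM	CLU	ATP1A2	GLUL	NFIA	GFAP	AGT	ASTSYN056	ASTSYN024	ASTSYN098	ASTSYN025	ASTSYN092	ASTSYN107	ASTSYN061	ASTSYN062	ASTSYN014	ASTSYN034	ASTSYN066	ASTSYN095	ASTSYN032	ASTSYN027	ASTSYN010	ASTSYN057	ASTSYN028	ASTSYN037	ASTSYN106	ASTSYN005	ASTSYN035	ASTSYN078	ASTSYN112	ASTSYN104	ASTSYN054	ASTSYN090	ASTSYN031	ASTSYN043	ASTSYN052	ASTSYN081
Astrocyte_component_synthetic_5	synthetic astrocyte component list	BMPR1B	SLC1A3	PPP1R3C	CD44	GLUL	NFIA	RANBP3L	APOE	MLC1	CLU	VIM	GFAP	SLC4A4	AGT	GPC5	NFIB	ASTSYN028	ASTSYN002	ASTSYN031	ASTSYN008	ASTSYN080	ASTSYN003	ASTSYN101	ASTSYN013	ASTSYN012	ASTSYN065	ASTSYN030	ASTSYN051	ASTSYN060	ASTSYN095	ASTSYN037	ASTSYN047	ASTSYN056	ASTSYN070	ASTSYN016	ASTSYN010	ASTSYN071	ASTSYN073	ASTSYN025	ASTSYN115	ASTSYN082	ASTSYN053	ASTSYN120	ASTSYN079	ASTSYN057	ASTSYN084
Astrocyte_component_synthetic_6	synthetic astrocyte component list	FGFR3	RANBP3L	GFAP	ALDH1L1	CD44	NFIA	APOE	SLC1A2	BMPR1B	MLC1	GLUL	AQP4	ATP1A2	GPC5	SLC4A4	NFIB	ASTSYN011	ASTSYN028	ASTSYN018	ASTSYN055	ASTSYN098	ASTSYN042	ASTSYN036	ASTSYN020	ASTSYN079	ASTSYN061	ASTSYN071	ASTSYN027	ASTSYN094	ASTSYN005	ASTSYN086	ASTSYN113	ASTSYN041	ASTSYN120	ASTSYN092	ASTSYN038	ASTSYN073	ASTSYN023	ASTSYN090	ASTSYN103	ASTSYN019	ASTSYN102	ASTSYN085	ASTSYN114	ASTSYN115	ASTSYN106
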