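variant_id	gene	qualifying_family_count
rsCOSEG01	GENE003	1
rsCOSEG02	GENE004	1
rsCOSEG03	GENE005	1
rsCOSEG04	GENE006	1
rsCOSEG05	GENE007	1
rsCOSEG06	GENE008	1
rsCOSEG07	GENE009	1
rsCOSEG08	GENE010	1
rsCOSEG09	GENE011	1
rsCOSEG10	GENE012	1
rsCOSEG11	GENE013	1
rsCOSEG12	GENE014	1
rsCOSEG13	GENE030	1
rsCOSEG14	GENE035	1
rsCOSEG15	GENE040	1
rsCOSEG16	GENE045	1
rsCOSEG17	GENE050	1
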