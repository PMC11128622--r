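variant_id	site_qc	rare	non_neutral	first_fail
rsCOSEG01	TRUE	TRUE	TRUE	pass
rsCOSEG02	TRUE	TRUE	TRUE	pass
rsCOSEG03	TRUE	TRUE	TRUE	pass
rsCOSEG04	TRUE	TRUE	TRUE	pass
rsCOSEG05	TRUE	TRUE	TRUE	pass
rsCOSEG06	TRUE	TRUE	TRUE	pass
rsCOSEG07	TRUE	TRUE	TRUE	pass
rsCOSEG08	TRUE	TRUE	TRUE	pass
rsCOSEG09	TRUE	TRUE	TRUE	pass
rsCOSEG10	TRUE	TRUE	TRUE	pass
rsCOSEG11	TRUE	TRUE	TRUE	pass
rsCOSEG12	TRUE	TRUE	TRUE	pass
rsCOSEG13	TRUE	TRUE	TRUE	pass
rsCOSEG14	TRUE	TRUE	TRUE	pass
rsCOSEG15	TRUE	TRUE	TRUE	pass
rsCOSEG16	TRUE	TRUE	TRUE	pass
rsCOSEG17	TRUE	TRUE	TRUE	pass
rsEPI1	TRUE	FALSE	FALSE	pass
rsEPI2	TRUE	FALSE	FALSE	pass
rsNULL001	TRUE	FALSE	FALSE	pass
rsNULL002	TRUE	FALSE	FALSE	pass
rsNULL003	TRUE	FALSE	FALSE	pass
rsNULL004	TRUE	FALSE	FALSE	pass
rsNULL005	TRUE	FALSE	FALSE	pass
rsNULL006	TRUE	FALSE	FALSE	pass
rsNULL007	TRUE	FALSE	FALSE	pass
rsNULL008	TRUE	FALSE	FALSE	pass
rsNULL009	TRUE	FALSE	FALSE	pass
rsNULL010	TRUE	FALSE	FALSE	pass
rsNULL011	TRUE	FALSE	FALSE	pass
rsNULL012	TRUE	FALSE	FALSE	pass
rsNULL013	TRUE	FALSE	FALSE	pass
rsNULL014	TRUE	FALSE	FALSE	pass
rsNULL015	TRUE	FALSE	FALSE	pass
rsNULL016	TRUE	FALSE	FALSE	pass
rsNULL017	TRUE	FALSE	FALSE	pass
rsNULL018	TRUE	FALSE	FALSE	pass
rsNULL019	TRUE	FALSE	FALSE	pass
rsNULL020	TRUE	FALSE	FALSE	pass
rsNULL021	TRUE	FALSE	FALSE	pass
rsNULL022	TRUE	FALSE	FALSE	pass
rsNULL023	TRUE	FALSE	FALSE	pass
rsNULL024	TRUE	FALSE	FALSE	pass
rsNULL025	TRUE	FALSE	FALSE	pass
rsNULL026	TRUE	FALSE	FALSE	pass
rsNULL027	TRUE	FALSE	FALSE	pass
rsNULL028	TRUE	FALSE	FALSE	pass
rsNULL029	TRUE	FALSE	FALSE	pass
rsNULL030	TRUE	FALSE	FALSE	pass
rsNULL031	TRUE	FALSE	FALSE	pass
rsNULL032	TRUE	FALSE	FALSE	pass
rsNULL033	TRUE	FALSE	FALSE	pass
rsNULL034	TRUE	FALSE	FALSE	pass
rsNULL035	TRUE	FALSE	FALSE	pass
rsNULL036	TRUE	FALSE	FALSE	pass
rsNULL037	TRUE	FALSE	FALSE	pass
rsNULL038	TRUE	FALSE	FALSE	pass
rsNULL039	TRUE	FALSE	FALSE	pass
rsNULL040	TRUE	FALSE	FALSE	pass
rsNULL041	TRUE	FALSE	FALSE	pass
rsNULL042	TRUE	FALSE	FALSE	pass
rsNULL043	TRUE	FALSE	FALSE	pass
rsNULL044	TRUE	FALSE	FALSE	pass
rsNULL045	TRUE	FALSE	FALSE	pass
rsNULL046	TRUE	FALSE	FALSE	pass
rsNULL047	TRUE	FALSE	FALSE	pass
rsNULL048	TRUE	FALSE	FALSE	pass
rsNULL049	TRUE	FALSE	FALSE	pass
rsNULL050	TRUE	FALSE	FALSE	pass
rsNULL051	TRUE	FALSE	FALSE	pass
rsNULL052	TRUE	FALSE	FALSE	pass
rsNULL053	TRUE	FALSE	FALSE	pass
rsNULL054	TRUE	FALSE	FALSE	pass
rsNULL055	TRUE	FALSE	FALSE	pass
rsNULL056	TRUE	FALSE	FALSE	pass
rsNULL057	TRUE	FALSE	FALSE	pass
rsNULL058	TRUE	FALSE	FALSE	pass
rsNULL059	TRUE	FALSE	FALSE	pass
rsNULL060	TRUE	FALSE	FALSE	pass
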