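pair	category	cells	aicc_interaction	aicc_var1	aicc_var2	aicc_var1_var2	delta_var1	delta_var2	delta_var1_var2	retained	unevaluable
rsEPI1*rsEPI2	H	1/1	84.9905	103.277	100.643	100.778	18.2864	15.6524	15.7877	TRUE	.
rsEPI2*rsNULL006	H	1/1;2/1	89.3038	100.89	99.8345	98.5393	11.5864	10.5306	9.23547	FALSE	.
rsNULL003*rsNULL008	H	0/1	89.8823	102.823	104.137	103.245	12.9409	14.2542	13.3625	TRUE	.
rsNULL006*rsNULL008	H	1/1	93.0397	99.412	104.137	99.7826	6.37231	11.0969	6.7429	FALSE	.
rsEPI2*rsNULL008	H	1/1;2/1	91.9154	99.792	103.302	100.53	7.87658	11.3863	8.6149	FALSE	.
rsEPI1*rsNULL006	H	1/1	94.215	103.772	99.9085	100.397	9.55736	5.69349	6.18158	FALSE	.
rsNULL006*rsNULL009	H	1/1	91.9986	97.8676	103.752	100	5.86896	11.7535	8.00164	FALSE	.
rsEPI1*rsNULL008	H	1/1	92.8829	102.464	103.548	102.955	9.58115	10.665	10.072	FALSE	.
rsCOSEG05*rsNULL006	L	0/0	85.9052	94.5723	96.8589	87.7369	8.6671	10.9537	1.83169	FALSE	.
rsNULL006*rsNULL012	H	1/0;1/1	93.7334	99.4318	105.908	101.326	5.69841	12.1746	7.59255	FALSE	.
rsCOSEG04*rsNULL006	L	0/0	87.6183	97.2542	97.5839	91.0199	9.63589	9.9656	3.40161	FALSE	.
rsEPI2*rsNULL009	H	1/1	93.097	97.8676	103.051	99.7779	4.77062	9.95361	6.68092	FALSE	.
rsNULL003*rsNULL006	H	0/1	95.9558	103.504	100.21	100.168	7.54807	4.25399	4.21246	FALSE	.
rsNULL002*rsNULL006	H	0/1;1/1	95.5006	106.57	100.137	102.196	11.069	4.63633	6.69564	FALSE	.
rsNULL006*rsNULL011	H	1/1	97.5699	100.21	106.669	102.141	2.63992	9.09922	4.57073	FALSE	.
rsNULL005*rsNULL006	L	0/0;1/0	93.2712	100.342	100.21	96.2247	7.07129	6.93869	2.9536	FALSE	.
rsCOSEG03*rsNULL006	L	0/0	95.0148	97.1893	97.8474	94.8417	2.1745	2.83262	-0.173122	FALSE	.
rsNULL007*rsNULL008	H	1/1	97.3183	105.015	104.137	105.796	7.69672	6.81823	8.47748	FALSE	.
rsNULL004*rsNULL006	H	0/1;1/1	96.4136	106.005	99.9085	101.486	9.59167	3.49489	5.07275	FALSE	.
rsCOSEG08*rsNULL006	L	0/0	95.8957	94.9222	99.7134	92.2792	-0.973532	3.8177	-3.61655	FALSE	.
rsCOSEG02*rsNULL006	L	0/0	96.2387	100.589	100.002	97.3283	4.35058	3.76318	1.08965	FALSE	.
rsCOSEG10*rsNULL006	L	0/0	96.2387	98.2217	100.002	94.9868	1.98299	3.76318	-1.25191	FALSE	.
rsCOSEG05*rsNULL006	H	0/1	93.4448	94.5723	96.8589	87.7369	1.1276	3.41418	-5.70781	FALSE	.
rsCOSEG06*rsNULL006	L	0/0	96.5215	100.739	100.21	97.5329	4.2178	3.68834	1.01143	FALSE	.
rsCOSEG07*rsNULL006	L	0/0	96.5215	98.3423	100.21	95.1517	1.82079	3.68834	-1.36979	FALSE	.
rsNULL003*rsNULL006	L	0/0;1/0	96.5215	103.504	100.21	100.168	6.98242	3.68834	3.64681	FALSE	.
rsEPI2*rsNULL007	H	1/0;2/1	97.2832	100.89	105.031	102.691	3.60699	7.74788	5.40815	FALSE	.
rsCOSEG01*rsNULL006	L	0/0	96.4723	98.2217	100.137	95.0914	1.74942	3.66468	-1.38082	FALSE	.
rsNULL001*rsNULL006	H	1/1	98.5462	105.467	100.137	101.883	6.92081	1.59071	3.33636	FALSE	.
rsEPI1*rsNULL009	H	1/1	95.1259	100.894	103.269	103.019	5.7686	8.14281	7.89355	FALSE	.
rsCOSEG04*rsNULL006	H	0/1	94.4458	97.2542	97.5839	91.0199	2.80836	3.13806	-3.42593	FALSE	.
rsNULL005*rsNULL006	H	1/1	98.9243	100.342	100.21	96.2247	1.41816	1.28556	-2.69953	FALSE	.
rsNULL006*rsNULL010	H	1/0;1/1	98.0113	100.002	106.168	101.718	1.99053	8.15621	3.70709	FALSE	.
rsNULL003*rsNULL008	L	0/0;1/1	95.4665	102.823	104.137	103.245	7.35675	8.67011	7.77837	FALSE	.
rsCOSEG09*rsNULL006	L	0/0	91.0399	94.3297	94.2901	91.7268	3.28982	3.25027	0.686951	FALSE	.
rsNULL004*rsNULL006	L	0/0;1/0	97.0726	106.005	99.9085	101.486	8.93264	2.83586	4.41373	FALSE	.
rsNULL003*rsNULL011	H	0/1	98.7371	103.504	106.669	105.576	4.76682	7.93205	6.83877	FALSE	.
rsCOSEG05*rsCOSEG08	L	0/0	81.9786	94.1933	91.0446	84.1183	12.2147	9.06601	2.1397	FALSE	.
rsCOSEG07*rsCOSEG08	L	0/0	85.9032	97.9748	94.9222	88.0382	12.0716	9.01902	2.13499	FALSE	.
rsCOSEG08*rsCOSEG10	L	0/0	85.808	94.7958	97.8484	87.9442	8.98777	12.0404	2.13613	FALSE	.
rsCOSEG01*rsCOSEG08	L	0/0	85.808	97.8484	94.7958	87.9442	12.0404	8.98777	2.13613	FALSE	.
rsNULL008*rsNULL010	H	1/0	98.4925	103.976	105.071	105.62	5.48364	6.5783	7.12778	FALSE	.
rsCOSEG03*rsCOSEG08	L	0/0	84.9187	96.8162	93.8344	87.0572	11.8975	8.91569	2.13849	FALSE	.
rsNULL004*rsNULL008	H	0/1	98.2294	104.92	103.734	105.493	6.69032	5.50501	7.26334	FALSE	.
rsNULL008*rsNULL011	H	1/1	98.9091	104.137	105.648	106.091	5.22751	6.73937	7.18207	FALSE	.
rsEPI1*rsNULL012	H	1/1	99.0082	103.42	105.271	105.288	4.41169	6.26311	6.28007	FALSE	.
rsNULL005*rsNULL009	H	2/1	97.4579	97.4861	103.752	99.6188	0.0281669	6.29416	2.16091	FALSE	.
rsCOSEG03*rsNULL006	H	0/1	98.1943	97.1893	97.8474	94.8417	-1.00501	-0.346885	-3.35262	FALSE	.
rsCOSEG05*rsCOSEG07	L	0/0	85.5583	94.5723	94.5723	87.6944	9.01408	9.01408	2.13613	FALSE	.
rsCOSEG01*rsCOSEG07	L	0/0	89.2734	98.2217	98.2217	91.4061	8.94832	8.94832	2.13275	FALSE	.
rsCOSEG07*rsCOSEG10	L	0/0	89.2734	98.2217	98.2217	91.4061	8.94832	8.94832	2.13275	FALSE	.
rsCOSEG03*rsCOSEG05	L	0/0	84.5569	93.4668	93.4668	86.6966	8.9099	8.9099	2.1397	FALSE	.
rsCOSEG03*rsCOSEG07	L	0/0	88.3118	97.1893	97.1893	90.4468	8.87752	8.87752	2.13499	FALSE	.
rsCOSEG01*rsCOSEG03	L	0/0	88.2197	97.0669	97.0669	90.3558	8.84722	8.84722	2.13613	FALSE	.
rsCOSEG03*rsCOSEG10	L	0/0	88.2197	97.0669	97.0669	90.3558	8.84722	8.84722	2.13613	FALSE	.
rsCOSEG07*rsNULL008	H	0/1	98.7645	97.4639	104.137	99.235	-1.30064	5.37207	0.4705	FALSE	.
rsEPI2*rsNULL012	H	1/1	99.2996	100.643	105.22	102.608	1.34327	5.92018	3.30807	FALSE	.
rsCOSEG06*rsCOSEG08	L	0/0	88.4071	100.282	94.9222	90.542	11.8752	6.51514	2.13499	FALSE	.
rsCOSEG02*rsCOSEG08	L	0/0	88.2807	100.125	94.7958	90.4168	11.8444	6.51514	2.13613	FALSE	.
rsEPI2*rsNULL003	H	1/0	99.4284	100.89	103.177	99.6309	1.46177	3.74819	0.202498	FALSE	.
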