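population	cpp	cpc	cmp	cmc
Ashkenazi	0.507	0.296	0.465	0.084
Iranian	4.215	2.576	4.684	4.450
Iraqi	4.483	2.759	5.724	3.448
Libyan	2.013	2.685	0.671	0.671
Moroccan	0.794	0.794	1.984	1.587
Sephardi	0.329	0.494	0.988	1.318
Syrian	0.985	0.493	0.985	1.232
Tunisian	2.685	1.342	4.027	2.685
Yemenite	3.347	1.071	1.874	1.606
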