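probe_id	annotation	control	wcr_untreated	wcr_treated
MZ00044023	Cinnamoyl COH reductase	52.9	48.64	54.64
MZ00035455	Cystene protease 1	113.65	100.27	151.25
MZ00004041	PAL	30.14	20.38	80.34
MZ00039775	Xylanase Inhibitor	1.98	1.66	3.37
MZ00001590	AGO1	125.88	304.86	392.15
MZ00016076	Hec1	1.51	11.12	9.55
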