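# Food intakes of the high-fiber dietary intervention (g/day), by period
# periods: day_0_15_30, day_45_60, day_75_105
formula	food	day_0_15_30	day_45_60	day_75_105
1	Adlay	222	128	123
1	Hyacinth beans	111	64.3	61.8
1	Buckwheat	111	64.3	61.8
1	Oats	166	96.5	92.7
1	Yam	111	64.3	61.8
1	Soybean	55.6	32.2	30.9
1	Red bean	55.6	32.2	30.9
1	Peanut	55.6	32.2	30.9
1	Goji berries	55.6	32.2	30.9
1	Yellow corn	55.6	32.2	30.9
1	Lotus seed	55.6	32.2	30.9
1	Big jujube	55.6	32.2	30.9
1	Olive oil	16.2	14.8	14.6
2	Bitter gourd	36.6	43.1	43.1
2	Fibersol-2	2.44	2.87	2.87
2	Oligosaccharides	0.61	0.72	0.72
2	Isomaltose	1.02	1.20	1.20
3	Fibersol-2	16.1	16.1	53.6
3	Oligosaccharides	4.02	4.02	13.4
3	Isomaltose	6.70	6.70	22.3
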