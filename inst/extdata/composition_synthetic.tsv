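# SYNTHETIC nutrient-composition table for worked examples and tests.
# Mass fraction (g nutrient per g food) reaching the gut microbiota.
# This is NOT a nutrient database: real analyses must supply a measured
# or database-derived composition table in the same format.
food	metabolite	fraction
Adlay	fib	0.60
Adlay	aa	0.10
Hyacinth beans	fib	0.40
Hyacinth beans	pept	0.20
Buckwheat	fib	0.55
Oats	fib	0.50
Oats	pept	0.12
Soybean	pept	0.35
Soybean	fib	0.15
Fibersol-2	fib	0.90
Oligosaccharides	fib	0.95
Isomaltose	glc	0.99
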