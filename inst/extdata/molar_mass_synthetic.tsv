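# SYNTHETIC molar masses (g/mol) for the toy metabolite ids used in the
# worked examples; fib/pept are nominal monomer-equivalent masses.
metabolite	molar_mass
fib	162.14
pept	120.0
aa	89.09
glc	180.16
ac	60.05
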