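# Ordered keyword map: first case-insensitive pattern match wins.
# Specific categories precede the generic "Phage protein" catch-all.
pattern	category
terminase	Phage terminase
methyltransferase	Methyltransferase
capsid	Phage capsid protein
tail fib(er|re)	Phage tail fiber
tape measure	Phage tape measure protein
tail	Phage tail protein
DNA polymerase	DNA polymerase
recombinase	Phage-associated recombinase
portal	Phage portal protein
single[- ]strand(ed)? DNA[- ]binding|ssDNA[- ]binding	ssDNA-binding protein
helicase	Phage DNA helicase
reductase	Reductase
peptidase	Peptidase
glyco(syl)?transferase	Glycotransferase
phage protein|hypothetical	Phage protein
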