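gene_symbol	reported_allele	reported_species
AMPD3	maternal	Mus musculus
ATP10A	maternal	Homo sapiens, Mus musculus and Macaca mulatta
B4GALNT4	maternal	Homo sapiens
CDKN1C	maternal	Homo sapiens and Mus musculus
EGFL7	paternal	Homo sapiens (predicted)
GLIS3	paternal	Homo sapiens
GPT	maternal	Homo sapiens
GRB10	maternal	Ovis aries
HSPA6	maternal	Homo sapiens (predicted)
IGF2	paternal	Ovis aries, Homo sapiens and Mus musculus
KCNQ1	maternal	Homo sapiens and Mus musculus
PON1	maternal	Homo sapiens
PRIM2	biallelic_or_conflicting	Homo sapiens
TH	maternal	Mus musculus
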