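gene_symbol	origin
AMPD3	paternal
ATP10A	paternal
B4GALNT4	maternal
CDKN1C	paternal
EGFL7	paternal
GLIS3	maternal
GPT	paternal
GRB10	maternal
HSPA6	paternal
IGF2	paternal
KCNQ1	paternal
PON1	paternal
PRIM2	paternal
TH	paternal
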