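##maf version=1

a score=0
s hg38.chr1 1000 4 + 248956422 A-TCG
s panTro6.chr1 500 4 + 228573443 A-TCG
s mm39.chr4 2000 4 + 156860686 AT-CG

a score=0
s hg38.chr1 1 7 + 248956422 ATCGGCA
s panTro6.chr1 600 7 + 228573443 ATCGGCA
s mm39.chr4 2100 6 + 156860686 ATCG-CA
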