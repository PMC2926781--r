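trinucleotide	value
AAA	0.249
AAC	0.262
AAG	-0.128
AAT	0.198
ACA	0.085
ACC	0.011
ACG	0.142
ACT	-0.219
AGA	0.094
AGC	0.123
AGG	-0.025
ATA	0.131
ATC	0.261
ATG	-0.147
CAA	-0.023
CAC	0.264
CAG	0.287
CCA	-0.23
CCC	-0.015
CCG	0.036
CGA	0.242
CGC	-0.217
CTA	0.293
CTC	0.268
GAA	-0.251
GAC	0.009
GCA	-0.066
GCC	0.243
GGA	-0.032
GTA	0.202
TAA	0.143
TCA	0.187
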