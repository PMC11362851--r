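##maf version=1 scoring=synthetic
# synthetic three-contig example (constructed fixture, not real data)

a score=100.0
s G1.c1 0 100 + 1000 ACGT
s G2.c2 0 100 + 900 ACGT
s G3.c3 0 100 - 800 ACGT

a score=90.0
s G1.c1 100 150 + 1000 ACGT
s G2.c2 120 150 + 900 ACGT
s G3.c3 120 150 - 800 ACGT

a score=80.0
s G1.c1 300 200 + 1000 ACGT
s G3.c3 300 200 - 800 ACGT

a score=10.0
s G2.c2 300 80 + 900 ACGT
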