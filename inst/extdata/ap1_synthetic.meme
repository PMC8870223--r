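MEME version 4

ALPHABET= ACGT

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF AP1_synthetic
letter-probability matrix: alength= 4 w= 10
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.016667 0.950000 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.950000 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
0.950000 0.016667 0.016667 0.016667
0.016667 0.016667 0.016667 0.950000
0.016667 0.950000 0.016667 0.016667
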