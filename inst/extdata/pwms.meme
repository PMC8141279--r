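MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25 C 0.25 G 0.25 T 0.25

MOTIF AP1_TGACTCA
letter-probability matrix: alength= 4 w= 7 nsites= 20 E= 0
0.020000 0.020000 0.020000 0.940000
0.020000 0.020000 0.940000 0.020000
0.940000 0.020000 0.020000 0.020000
0.020000 0.940000 0.020000 0.020000
0.020000 0.020000 0.020000 0.940000
0.020000 0.940000 0.020000 0.020000
0.940000 0.020000 0.020000 0.020000

MOTIF TBX_AGGTGTGA
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
0.910000 0.030000 0.030000 0.030000
0.030000 0.030000 0.910000 0.030000
0.030000 0.030000 0.910000 0.030000
0.030000 0.030000 0.030000 0.910000
0.030000 0.030000 0.910000 0.030000
0.030000 0.030000 0.030000 0.910000
0.030000 0.030000 0.910000 0.030000
0.910000 0.030000 0.030000 0.030000

MOTIF EGR_GCGTGGGCG
letter-probability matrix: alength= 4 w= 9 nsites= 20 E= 0
0.030000 0.030000 0.910000 0.030000
0.030000 0.910000 0.030000 0.030000
0.030000 0.030000 0.910000 0.030000
0.030000 0.030000 0.030000 0.910000
0.030000 0.030000 0.910000 0.030000
0.030000 0.030000 0.910000 0.030000
0.030000 0.030000 0.910000 0.030000
0.030000 0.910000 0.030000 0.030000
0.030000 0.030000 0.910000 0.030000

MOTIF MspI_CCGG
letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0
0.010000 0.970000 0.010000 0.010000
0.010000 0.970000 0.010000 0.010000
0.010000 0.010000 0.970000 0.010000
0.010000 0.010000 0.970000 0.010000

MOTIF TaqI_TCGA
letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0
0.010000 0.010000 0.010000 0.970000
0.010000 0.970000 0.010000 0.010000
0.010000 0.010000 0.970000 0.010000
0.970000 0.010000 0.010000 0.010000

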