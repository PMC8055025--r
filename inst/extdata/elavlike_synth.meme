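MEME version 4

ALPHABET= ACGU

Background letter frequencies
A 0.25 C 0.25 G 0.25 U 0.25

MOTIF ELAVlike_synth
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
0.040000 0.020000 0.020000 0.920000
0.040000 0.020000 0.020000 0.920000
0.040000 0.020000 0.020000 0.920000
0.050000 0.050000 0.800000 0.100000
0.040000 0.020000 0.020000 0.920000
0.040000 0.020000 0.020000 0.920000
0.040000 0.020000 0.020000 0.920000
0.040000 0.020000 0.020000 0.920000

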