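>SINE_consensus_synthetic 360 nt synthetic stand-in consensus
AATCTAAAATGTTAGGCTTTACTATCGAAATTCTCTATCGTGCATATCTAACATGCTGCT
TATTCGAATCAATTACAAACACAGTAGCCTCCTCAGTAACGACCCAAGAACATAACCTAT
TCTTCAGGGGACTAGAGTGTGAGGTAGGAGACTGCCACCAACGAATAGGATTCGAGTCAG
GTCTAGTTAATTTACCAAGAATGGACATAGTACTTTGGCAGTATGGGGTACTGGAATTAT
CCGTTTTGCCTTATATCTATGCGCATTATTGTAGGATTCACCACACGGGTTTATGCCTAT
AAGAAATTTATCAATTATCGGTTACCCTTTAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA
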