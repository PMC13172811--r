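>SK30_extension_anchor HIV-1 reference (NC_001802) region around probe SK30, 105 bp
GGTCTGAGGGATCTCTAGTTACCAGAGTCACACAACAGACGGGCACACACTACTTGAAGC
ACTCAAGGCAAGCTTTATTGAGGCTTAAGCAGTGGGTTCCCTAGT
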