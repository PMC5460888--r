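>synthetic_cds_60codons synthetic toy coding sequence
ATGAAGACTACTACCCCTTCACTACGTACATAAGCATGCGCGTCAACCATTCATTAACAGCGCGTAGAAACCAAAGAATTGATTGACAGGAGCTACCTTTAATTGGTACCAAAACTGTCGCCTGCAGTCCACCCGTACTCTTTGCGGCTCAAATTTAAATTTCGCTCACCCGGGTACGACACTTAA
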