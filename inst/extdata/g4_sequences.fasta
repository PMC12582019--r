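>G4_IX G4 motif, S. cerevisiae chromosome IX
GGGTACGGTGGGTAATAAGGGAAGGTATCGGG
>G4_IXmut mutant control, G-tracts disrupted
GCGTACGGTGCGTAATAAGCGAAGGTATCGCG
>fret_donor_strand handle + G4_IX, 3' Cy3 donor
TGGCGACGGCAGCGACCATTTGGGTACGGTGGGTAATAAGGGAAGGTATCGGG
>fret_acceptor_strand complement of handle, 5' Cy5 acceptor, 3' biotin
TGGTCGCTGCCGTCGCCA
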