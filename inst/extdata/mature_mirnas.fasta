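>hsa-let-7f
TGAGGTAGTAGATTGTATAGTT
>hsa-let-7g
TGAGGTAGTAGTTTGTACAGTT
>hsa-miR-199a-3p
ACAGTAGTCTGCACATTGGTTA
>hsa-miR-29a
TAGCACCATCTGAAATCGGTTA
>hsa-let-7a
TGAGGTAGTAGGTTGTATAGTT
>hsa-let-7i
TGAGGTAGTAGTTTGTGCTGTT
>hsa-miR-21
TAGCTTATCAGACTGATGTTGA
>hsa-miR-152
TCAGTGCATGACAGAACTTGG
>hsa-miR-143
TGAGATGAAGCACTGTAGCTC
>hsa-miR-221
AGCTACATTGTCTGCTGGGTTTC
>hsa-miR-103
AGCAGCATTGTACAGGGCTATGA
>hsa-miR-100
AACCCGTAGATCCGAACTTGTG
>hsa-let-7c
TGAGGTAGTAGGTTGTATGGTT
>hsa-let-7e
TGAGGTAGGAGGTTGTATAGTT
>hsa-miR-24
TGGCTCAGTTCAGCAGGAACAG
>hsa-miR-125b
TCCCTGAGACCCTAACTTGTGA
>hsa-miR-22
AAGCTGCCAGTTGAAGAACTGT
>hsa-miR-1
TGGAATGTAAAGAAGTATGTAT
>hsa-miR-320a
AAAAGCTGGGTTGAGAGGGCGA
>hsa-miR-423-5p
TGAGGGGCAGAGAGCGAGACTTT
>hsa-miR-185
TGGAGAGAAAGGCAGTTCCTGA
>hsa-let-7d
AGAGGTAGTAGGTTGCATAGTT
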