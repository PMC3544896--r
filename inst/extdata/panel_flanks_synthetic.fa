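>rs7085104 SYNTHETIC flank: 10 bp each side, variant base 11 = non-target allele (A); target G. Context constructed so the target allele creates a CpG.
ATTAGGTTACATTATAAGGTT
>rs3740400 SYNTHETIC flank: variant base = non-target A; target C. Context constructed so the target allele creates a CpG.
TTAGGATTCAAGAATTAGGAT
>rs3740393 SYNTHETIC flank: variant base = non-target G; target C. Neutral context.
AGGATTATTAGATTAGGATTA
>rs3740390 SYNTHETIC flank: variant base = non-target G; target A. Neutral context.
TTAGGATTATGTAGGATTAGG
>rs11191439 SYNTHETIC flank: variant base = non-target C; target T. Context constructed so the target allele removes a CpG.
AGGTTATTAACGATTAGGTTA
>rs11191453 SYNTHETIC flank: variant base = non-target T; target C. Neutral context.
GGATTAGGTATATTAGGATTA
>rs10748835 SYNTHETIC flank: variant base = non-target G; target A. Neutral context.
ATTAGGATTTGTTTAGGATTA
>rs1046778 SYNTHETIC flank: variant base = non-target T; target C. Neutral context.
GGTTAGGATATATTAGGTTAG
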