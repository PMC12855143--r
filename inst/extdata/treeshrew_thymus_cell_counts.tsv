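# Published per-sample cell counts for a four-animal tree shrew thymus
# scRNA-seq atlas (one animal per age group). cells_sequenced is the
# number of cells obtained per library; cells_retained the number kept
# after quality-control filtering. The "total" row is the printed
# dataset-wide figure reported alongside the per-sample values.
sample	age_group	cells_sequenced	cells_retained
infant	3d	11276	11071
juvenile	57d	10069	9940
adult	1y	9664	9449
elderly	5y3m	5802	5723
total	all	36811	36183
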