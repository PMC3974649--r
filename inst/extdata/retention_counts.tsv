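genotype	assay	retaining	total
wild-type	ugcr	2	27
wild-type	dgcr	0	62
tel1	ugcr	18	31
sae2	ugcr	14	28
rad53_sml1	ugcr	13	42
mrc1_tof1	ugcr	9	14
xrs2-11	ugcr	6	20
all_strains	ugcr	367	2670
all_strains	dgcr	15	2435
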