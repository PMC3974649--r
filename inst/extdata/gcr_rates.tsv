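genotype	assay	rate
wild-type	ugcr	2.27e-9
tel1	ugcr	4.99e-9
sae2	ugcr	4.23e-8
sae2_tel1	ugcr	7.14e-8
wild-type	dgcr	1.97e-8
tel1	dgcr	2.87e-8
sae2	dgcr	1.65e-7
sae2_tel1	dgcr	6.63e-8
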