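miR	m	n
hsa-miR-200c	13	10
hsa-miR-200b	12	10
hsa-miR-200a	12	10
hsa-miR-17	10	10
hsa-miR-19a	10	10
hsa-miR-20a	10	10
hsa-miR-18a	9	10
hsa-miR-141	7	10
hsa-miR-92a	7	10
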