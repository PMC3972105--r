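miR	m	n
hsa-miR-29a	9	10
hsa-miR-9	8	10
hsa-let-7a	8	10
hsa-let-7i	7	10
hsa-miR-19b	7	10
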