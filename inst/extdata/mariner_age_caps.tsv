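family	genome	cap_mya	rationale
Mariner-1_Tbel	TBel	100	family cannot predate the placental radiation in a placental genome
Mariner-1_Tbel	EEu	100	family cannot predate the placental radiation in a placental genome
Mariner1_BT	BT	90	phylogenetic constraint on the ruminant/cetacean lineage
Mariner1_BT	TTr	90	phylogenetic constraint on the ruminant/cetacean lineage
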