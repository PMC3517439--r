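genome	cal_family	cal_genome	age_min	age_max	rationale
TBel	TIGGER1	TBel	100	190	TIGGER1 expanded after the marsupial-placental split (190 MYA) and before the placental radiation (~100 MYA)
EEu	TIGGER1	EEu	100	190	TIGGER1 expanded after the marsupial-placental split (190 MYA) and before the placental radiation (~100 MYA)
BT	TIGGER1	BT	100	190	TIGGER1 expanded after the marsupial-placental split (190 MYA) and before the placental radiation (~100 MYA)
TTr	TIGGER1	TTr	100	190	TIGGER1 expanded after the marsupial-placental split (190 MYA) and before the placental radiation (~100 MYA)
PBa	Mariner-28_SIn	SIn	140	140	outermost age: common ancestor of all ant species (140 MYA)
HSa	Mariner-28_SIn	SIn	140	140	outermost age: common ancestor of all ant species (140 MYA)
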