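condition	gene
female_visceral_adipose	CREBBP
female_visceral_adipose	EP300
female_visceral_adipose	MAPK1
female_visceral_adipose	MAPK3
female_visceral_adipose	MYC
female_visceral_adipose	PPP2CA
female_visceral_adipose	PPP2R1A
female_visceral_adipose	PPP2R1B
female_visceral_adipose	ROCK1
female_visceral_adipose	RPS6KB2
male_skeletal_muscle	CDKN2B
male_skeletal_muscle	EP300
male_skeletal_muscle	MAPK1
male_skeletal_muscle	MAPK3
male_skeletal_muscle	PPP2R1B
male_skeletal_muscle	SMAD5
male_skeletal_muscle	SP1
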