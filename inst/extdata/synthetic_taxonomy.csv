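taxon_id,genus,family,parent
Otu001,genus_01,family_01,family_01
Otu002,genus_01,family_01,family_01
Otu003,genus_02,family_01,family_01
Otu004,genus_02,family_01,family_01
Otu005,genus_03,family_02,family_02
Otu006,genus_03,family_02,family_02
Otu007,genus_04,family_02,family_02
Otu008,genus_04,family_02,family_02
Otu009,genus_05,family_03,family_03
Otu010,genus_05,family_03,family_03
Otu011,genus_06,family_03,family_03
Otu012,genus_06,family_03,family_03
Otu013,genus_07,family_04,family_04
Otu014,genus_07,family_04,family_04
Otu015,genus_08,family_04,family_04
Otu016,genus_08,family_04,family_04
Otu017,genus_09,family_05,family_05
Otu018,genus_09,family_05,family_05
Otu019,genus_10,family_05,family_05
Otu020,NA,family_05,family_05
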