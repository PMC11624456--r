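# sex-category patterns over the sex dictionary
sex_01	SEX	SLOT:sex_terms!capture
sex_02	SEX	RX:"only" ; SLOT:sex_terms!capture
sex_03	SEX	SLOT:sex_terms!capture ; RX:"participants|populations?|offenders|prisoners|inmates|individuals|samples?"
sex_04	SEX	RX:"both" ; SLOT:sex_terms!capture ; RX:"and" ; SLOT:sex_terms!capture
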