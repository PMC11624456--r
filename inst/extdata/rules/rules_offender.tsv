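# offender-type patterns; slots always pool offense and population dictionaries so the longest surface wins
off_01	OFFENDER_TYPE	SLOT:offense_terms,population_terms!capture
off_02	OFFENDER_TYPE	LIT:"characteristics of" ; SLOT:offense_terms,population_terms!capture ; LIT:"in"
off_03	OFFENDER_TYPE	RX:"convicted of|charged with|involved in|involved with" ; SLOT:offense_terms,population_terms!capture
off_04	OFFENDER_TYPE	RX:"history of" ; SLOT:offense_terms,population_terms!capture
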