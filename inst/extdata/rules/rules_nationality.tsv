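# place-of-origin patterns; countries take precedence over the other geo dictionaries
nat_01	NATIONALITY	SLOT:countries,nationalities,us_states,us_counties,us_cities,world_cities!capture
nat_02	NATIONALITY	RX:"in|from|across" ; SLOT:countries!capture
nat_03	NATIONALITY	SLOT:nationalities!capture ; RX:"sample|cohort|population|participants|prisoners|offenders|inmates"
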