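# numeric and textual age patterns; capture = the age expression
age_01	AGE	RX:"aged? \d{1,3}(?: ?(?:to|-|–) ?\d{1,3})?(?: years?(?: old)?)?"!capture
age_02	AGE	RX:"\d{1,3} ?(?:to|-|–) ?\d{1,3} years?(?: old| of age)?"!capture
age_03	AGE	RX:"between \d{1,3} and \d{1,3} years?(?: old| of age)?"!capture
age_04	AGE	RX:"\d{1,3}(?: and \d{1,3})?[- ]year[- ]olds?"!capture
age_05	AGE	RX:"\d{1,3}\+(?: years?(?: old)?)?"!capture
age_06	AGE	RX:"older than \d{1,3}(?: years?)?"!capture
age_07	AGE	RX:"younger than \d{1,3}(?: years?)?"!capture
age_08	AGE	RX:"under (?:the age of )?\d{1,3}(?: years?)?"!capture
age_09	AGE	RX:"over (?:the age of )?\d{1,3} years?"!capture
age_10	AGE	RX:"mean age(?: of| was)? \d{1,3}"!capture
age_11	AGE	SLOT:age_terms!capture
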