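# US county	demonym
Cook County	American
Los Angeles County	American
Harris County	American
Maricopa County	American
San Diego County	American
Orange County	American
Miami-Dade County	American
Dallas County	American
Kings County	American
Riverside County	American
Clark County	American
King County	American
Queens County	American
Tarrant County	American
Santa Clara County	American
Broward County	American
Bexar County	American
Wayne County	American
Alameda County	American
Middlesex County	American
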