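# surface term	canonical descriptor	optional suffix expansions
offender	offender	s
prisoner	prisoner	s
inmate	inmate	s
detainee	detainee	s
convict	convict	s
felon	felon	s
criminal	criminal	s
incarcerated individual	incarcerated individual	s
incarcerated person	incarcerated person	s
incarcerated population	incarcerated population	s
reoffender	reoffender	s
reoffending	reoffending
recidivist	recidivist	s
remandee	remandee	s
parolee	parolee	s
probationer	probationer	s
young offender	young offender	s
juvenile offender	juvenile offender	s
juvenile	juvenile	s
delinquent	delinquent	s
juvenile delinquent	juvenile delinquent	s
perpetrator	perpetrator	s
arrestee	arrestee	s
gang member	gang member	s
serial offender	serial offender	s
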