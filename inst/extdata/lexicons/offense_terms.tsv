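# surface term	canonical offense	optional suffix expansions
sex crime	sex offence	s
sex offence	sex offence	s
sex offense	sex offence	s
sex offending	sex offence
sexual offending	sex offence
sex offender	sex offence	s
sexual offender	sex offence	s
sexual offence	sex offence	s
sexual assault	sexual assault	s
sextortion	sextortion
rape	rape	s
rapist	rape	s
serial rapist	rape	s
assault with intent to commit rape	rape
child molester	child sex abuse	s
child molestation	child sex abuse
child sex abuse	child sex abuse
child sexual abuse	child sex abuse
child sex offender	child sex abuse	s
child abuser	child abuse	s
child abuse	child abuse
pedophile	child sex abuse	s
paedophile	child sex abuse	s
ADVO	apprehended domestic violence order
apprehended domestic violence order	apprehended domestic violence order	s
domestic violence misdemeanor	domestic violence	s
domestic violence	domestic violence
breach of parole	breach of parole
murder	homicide	s
murderer	homicide	s
homicide	homicide	s
homicide offender	homicide	s
violent offender	violent offence	s
violent offence	violent offence	s
violent offense	violent offence	s
violent crime	violent offence	s
violent offending	violent offence
assault	assault	s
aggravated assault	assault	s
robbery	robbery
robber	robbery	s
serial commercial robber	robbery	s
stalking	stalking
stalker	stalking	s
arson	arson
arsonist	arson	s
theft	theft	s
thief	theft
thieves	theft
shoplifting	theft
shoplifter	theft	s
fraud	fraud	s
fraudster	fraud	s
burglary	burglary
burglar	burglary	s
nonviolent offender	nonviolent offence	s
non-violent offender	nonviolent offence	s
nonviolent offence	nonviolent offence	s
driving under the influence	driving under the influence
drunk driving	driving under the influence
drink driving	driving under the influence
drug trafficking	drug trafficking
drug trafficker	drug trafficking	s
drug offence	drug offence	s
drug offense	drug offence	s
drug offender	drug offence	s
drug-related offender	drug offence	s
drug dealer	drug trafficking	s
mentally ill offender	mental illness	s
mentally disordered offender	mental illness	s
offender with mental illness	mental illness
offenders with mental illness	mental illness
psychotic inmate	psychosis	s
psychotic offender	psychosis	s
psychotic prisoner	psychosis	s
psychosis	psychosis
psychopath	psychopathy	s
psychopathy	psychopathy
schizophrenic offender	schizophrenia	s
borderline personality disorder	borderline personality disorder
ex-offender	ex-offender	s
ex offender	ex-offender	s
high risk offender	high risk offender	s
high-risk offender	high risk offender	s
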