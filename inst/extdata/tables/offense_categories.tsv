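canonical	category	attribute
sex offence	sex	
rape	sex	rape
sexual assault	sex	sexual assault
sextortion	sex	sextortion
child sex abuse	child_crime_related	child sex abuse
child abuse	child_crime_related	child abuse
apprehended domestic violence order	violent	apprehended domestic violence order
domestic violence	violent	domestic violence
homicide	violent	homicide
violent offence	violent	
assault	violent	assault
robbery	violent	robbery
stalking	violent	stalking
arson	violent	arson
breach of parole	nonviolent	breach of parole
theft	nonviolent	theft
fraud	nonviolent	fraud
burglary	nonviolent	burglary
nonviolent offence	nonviolent	
driving under the influence	drug_related	driving under the influence
drug trafficking	drug_related	drug trafficking
drug offence	drug_related	
mental illness	mentally_ill	
psychosis	mentally_ill	psychosis
psychopathy	mentally_ill	psychopathy
schizophrenia	mentally_ill	schizophrenia
borderline personality disorder	mentally_ill	borderline personality disorder
ex-offender	miscellaneous	ex-offender
high risk offender	miscellaneous	high risk offender
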