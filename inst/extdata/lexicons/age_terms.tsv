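# surface term	standardized group(s), |-joined
children	minor
child	minor
minors	minor
minor	minor
juveniles	minor
juvenile	minor
delinquents	minor
delinquent	minor
school children	minor
schoolchildren	minor
boys	minor
girls	minor
adolescent	minor|18-24
adolescents	minor|18-24
teen	minor|18-24
teens	minor|18-24
teenager	minor|18-24
teenagers	minor|18-24
young	minor|18-24
youth	minor|18-24
youths	minor|18-24
young offenders	minor|18-24
young people	minor|18-24
adults	unknown_adult
adult	unknown_adult
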