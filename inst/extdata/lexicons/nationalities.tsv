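# nationality surface	demonym
American	American
British	British
English	British
Scottish	British
Welsh	British
Australian	Australian
Canadian	Canadian
Chinese	Chinese
German	German
French	French
Swedish	Swedish
Indian	Indian
Dutch	Dutch
Italian	Italian
Japanese	Japanese
Spanish	Spanish
Brazilian	Brazilian
South African	South African
Norwegian	Norwegian
Swiss	Swiss
Finnish	Finnish
Danish	Danish
South Korean	South Korean
New Zealander	New Zealander
Irish	Irish
Iranian	Iranian
Nigerian	Nigerian
Mexican	Mexican
Russian	Russian
Polish	Polish
Greek	Greek
Turkish	Turkish
Belgian	Belgian
Austrian	Austrian
Portuguese	Portuguese
Israeli	Israeli
Egyptian	Egyptian
Dominican	Dominican
Dominicans	Dominican
Dominicanes	Dominican
Czechoslovakian	miscellaneous
Czechoslovak	miscellaneous
Yugoslavian	miscellaneous
Yugoslav	miscellaneous
Soviet	miscellaneous
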