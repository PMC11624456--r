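# city	demonym
London	British
Oslo	Norwegian
Stockholm	Swedish
Copenhagen	Danish
Helsinki	Finnish
Paris	French
Berlin	German
Hamburg	German
Madrid	Spanish
Barcelona	Spanish
Rome	Italian
Milan	Italian
Amsterdam	Dutch
Tokyo	Japanese
Osaka	Japanese
Beijing	Chinese
Shanghai	Chinese
Mumbai	Indian
Delhi	Indian
Sydney	Australian
Melbourne	Australian
Toronto	Canadian
Vancouver	Canadian
Montreal	Canadian
Seoul	South Korean
Sao Paulo	Brazilian
Rio de Janeiro	Brazilian
Cape Town	South African
Johannesburg	South African
Zurich	Swiss
Geneva	Swiss
Moscow	Russian
Istanbul	Turkish
Cairo	Egyptian
Dublin	Irish
Auckland	New Zealander
Vienna	Austrian
Lisbon	Portuguese
Athens	Greek
Brussels	Belgian
Warsaw	Polish
Mexico City	Mexican
Edinburgh	British
Glasgow	British
Tehran	Iranian
Lagos	Nigerian
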