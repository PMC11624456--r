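# country name	demonym
United States	American
United States of America	American
USA	American
U.S.A.	American
United Kingdom	British
Great Britain	British
Britain	British
UK	British
England	British
Scotland	British
Wales	British
Northern Ireland	British
Australia	Australian
Canada	Canadian
China	Chinese
Germany	German
France	French
Sweden	Swedish
India	Indian
Netherlands	Dutch
Italy	Italian
Japan	Japanese
Spain	Spanish
Brazil	Brazilian
South Africa	South African
Norway	Norwegian
Switzerland	Swiss
Finland	Finnish
Denmark	Danish
South Korea	South Korean
New Zealand	New Zealander
Ireland	Irish
Iran	Iranian
Nigeria	Nigerian
Mexico	Mexican
Russia	Russian
Poland	Polish
Greece	Greek
Turkey	Turkish
Belgium	Belgian
Austria	Austrian
Portugal	Portuguese
Israel	Israeli
Egypt	Egyptian
Dominican Republic	Dominican
Yugoslavia	miscellaneous
Czechoslovakia	miscellaneous
Soviet Union	miscellaneous
East Germany	miscellaneous
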