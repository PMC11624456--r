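# US city	demonym
New York City	American
Los Angeles	American
Chicago	American
Houston	American
Phoenix	American
Philadelphia	American
San Antonio	American
San Diego	American
Dallas	American
Austin	American
Jacksonville	American
Fort Worth	American
Columbus	American
Charlotte	American
Indianapolis	American
San Francisco	American
Seattle	American
Denver	American
Boston	American
Nashville	American
Baltimore	American
Memphis	American
Milwaukee	American
Detroit	American
Atlanta	American
Las Vegas	American
Portland	American
Oklahoma City	American
Tucson	American
Albuquerque	American
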