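country,n,n_low_either,n_low_cognitive,n_low_socioemotional
Bangladesh,7713,2956,908,2319
Barbados,171,31,1,30
Belize,719,156,9,150
Bhutan,2200,749,145,656
Bosnia,963,42,5,37
Cameroon,1587,843,247,715
Central African Republic,3358,1817,818,1337
Chad,4451,2982,2347,1308
Congo,1486,729,216,622
Democratic Republic of the Congo,3726,1786,1050,1072
Ghana,2928,955,309,778
Honduras,2800,477,34,464
Iraq,13119,3714,1391,2834
Jordan,2597,983,257,799
Kazakhstan,1686,230,80,156
Kosovo,595,93,12,85
Kyrgyzstan,1683,321,110,235
Lao People's Democratic Republic,4052,719,249,502
Lebanon,695,159,48,123
Macedonia,523,47,6,42
Malawi,7330,2930,1338,1986
Montenegro,1206,51,9,42
Nepal,2142,900,378,655
Nigeria,9382,4289,1991,3113
Pakistan,1463,704,461,381
Republic of Moldova,620,124,3,121
Saint Lucia,113,12,2,12
Serbia,3193,155,13,146
Sierra Leone,3232,1755,713,1281
Suriname,997,319,13,309
Swaziland,1011,430,68,388
Togo,1669,789,319,548
Tunisia,1024,286,70,249
Viet Nam,1366,229,112,134
Zimbabwe,7422,2785,759,2338
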