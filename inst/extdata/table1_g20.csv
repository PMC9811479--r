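country,iso3,imported_pm25,imported_o3,domestic_pm25,domestic_o3,rerer_pm25,rerer_o3
Argentina,ARG,5.20,0.23,4.18,0.15,0.55,0.61
Australia,AUS,0.40,0.04,1.36,0.07,0.23,0.38
Austria,AUT,2.92,0.12,0.68,0.01,0.81,0.90
Belgium,BEL,4.30,0.24,0.47,0.01,0.90,0.97
Bulgaria,BGR,7.34,0.11,2.49,0.02,0.75,0.82
Brazil,BRA,4.39,0.58,30.29,1.64,0.13,0.26
Canada,CAN,3.94,0.39,4.26,0.15,0.48,0.72
China,CHN,67.03,32.72,821.28,83.78,0.08,0.28
Cyprus,CYP,0.43,0.02,0.01,0.00,0.99,0.99
Czech Republic,CZE,5.34,0.13,1.62,0.03,0.77,0.82
Germany,DEU,25.64,1.29,13.60,0.38,0.65,0.77
Denmark,DNK,1.74,0.14,0.31,0.02,0.85,0.87
Spain,ESP,7.73,0.80,3.86,0.42,0.67,0.65
Estonia,EST,0.57,0.01,0.07,0.00,0.90,0.96
Finland,FIN,1.25,0.05,0.59,0.01,0.68,0.90
France,FRA,8.45,0.44,9.25,0.27,0.48,0.62
United Kingdom,GBR,11.45,1.14,8.16,0.15,0.58,0.88
Greece,GRC,5.63,0.24,1.92,0.06,0.75,0.80
Croatia,HRV,2.74,0.10,0.35,0.01,0.89,0.91
Hungary,HUN,6.62,0.24,1.57,0.05,0.81,0.83
Indonesia,IDN,24.17,1.86,26.61,1.63,0.48,0.53
India,IND,86.87,26.33,350.95,72.19,0.20,0.27
Ireland,IRL,0.52,0.05,0.09,0.01,0.85,0.78
Italy,ITA,17.17,1.23,9.39,0.39,0.65,0.76
Japan,JPN,24.58,1.79,12.27,0.75,0.67,0.71
South Korea,KOR,10.62,0.57,2.01,0.24,0.84,0.71
Lithuania,LTU,2.41,0.04,0.20,0.00,0.92,0.90
Luxembourg,LUX,0.17,0.01,0.00,0.00,0.99,1.00
Latvia,LVA,1.64,0.02,0.13,0.00,0.92,0.91
Mexico,MEX,2.74,0.70,11.97,1.07,0.19,0.40
Malta,MLT,0.20,0.01,0.00,0.00,1.00,1.00
Netherlands,NLD,5.16,0.30,0.87,0.00,0.86,1.01
Poland,POL,14.35,0.40,9.18,0.10,0.61,0.80
Portugal,PRT,2.50,0.17,0.57,0.03,0.81,0.85
Romania,ROU,12.92,0.31,5.92,0.11,0.69,0.74
Russia,RUS,49.75,0.79,82.08,0.78,0.38,0.51
Saudi Arabia,SAU,3.72,0.06,2.50,0.04,0.60,0.59
Slovakia,SVK,3.14,0.05,0.43,0.00,0.88,0.92
Slovenia,SVN,0.70,0.02,0.12,0.00,0.85,0.95
Sweden,SWE,2.16,0.11,0.70,0.01,0.75,0.95
Turkey,TUR,13.93,0.92,13.09,0.46,0.52,0.67
USA,USA,19.02,3.06,79.83,7.26,0.19,0.30
South Africa,ZAF,1.45,0.11,12.63,0.21,0.10,0.33
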