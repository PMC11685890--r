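"region","country","year","su_thousands"
"Hovsgol","MNG",2018,9483.96
"Hovsgol","MNG",2019,10082.73
"Hovsgol","MNG",2020,9433.97
"Hovsgol","MNG",2021,10347.45
"Hovsgol","MNG",2022,11268.4
"Bayan-Olgiy","MNG",2018,3448.13
"Bayan-Olgiy","MNG",2019,3510.11
"Bayan-Olgiy","MNG",2020,3540.17
"Bayan-Olgiy","MNG",2021,3886.2
"Bayan-Olgiy","MNG",2022,3815.6
"Dornod","MNG",2018,5220.39
"Dornod","MNG",2019,5747.55
"Dornod","MNG",2020,6165.7
"Dornod","MNG",2021,6968.9
"Dornod","MNG",2022,7808.64
"Bulgan","MNG",2018,5948.87
"Bulgan","MNG",2019,6575.38
"Bulgan","MNG",2020,6170.74
"Bulgan","MNG",2021,6698.32
"Bulgan","MNG",2022,7431.89
"Selenge","MNG",2018,3159.69
"Selenge","MNG",2019,3406.14
"Selenge","MNG",2020,3691.41
"Selenge","MNG",2021,3952.51
"Selenge","MNG",2022,4119.51
"Hentiy","MNG",2018,8179.14
"Hentiy","MNG",2019,8573.55
"Hentiy","MNG",2020,8324.36
"Hentiy","MNG",2021,8922.71
"Hentiy","MNG",2022,9361.77
"Arhangay","MNG",2018,10714.02
"Arhangay","MNG",2019,12107.65
"Arhangay","MNG",2020,10977.67
"Arhangay","MNG",2021,11528.89
"Arhangay","MNG",2022,12620.81
"Tov","MNG",2018,7905.73
"Tov","MNG",2019,8624.24
"Tov","MNG",2020,8535.02
"Tov","MNG",2021,8348.5
"Tov","MNG",2022,9097.56
"Suhbaatar","MNG",2018,6851.17
"Suhbaatar","MNG",2019,6998.02
"Suhbaatar","MNG",2020,7186.34
"Suhbaatar","MNG",2021,7828.16
"Suhbaatar","MNG",2022,8652.77
"Chifeng","IMNG",2018,16929.07
"Chifeng","IMNG",2019,16372.3
"Chifeng","IMNG",2020,16452.82
"Chifeng","IMNG",2021,16695.11
"Chifeng","IMNG",2022,17253.57
"Ordos","IMNG",2018,8482.59
"Ordos","IMNG",2019,9213.55
"Ordos","IMNG",2020,9384.56
"Ordos","IMNG",2021,9684.55
"Ordos","IMNG",2022,9908.21
"Hulunbuir","IMNG",2018,12087.85
"Hulunbuir","IMNG",2019,12004.12
"Hulunbuir","IMNG",2020,11766.57
"Hulunbuir","IMNG",2021,12328.2
"Hulunbuir","IMNG",2022,12971.67
"Tongliao","IMNG",2018,14779.59
"Tongliao","IMNG",2019,15087.98
"Tongliao","IMNG",2020,15951.88
"Tongliao","IMNG",2021,16610.07
"Tongliao","IMNG",2022,17776.86
"Ulanqab","IMNG",2018,4769.49
"Ulanqab","IMNG",2019,4630.91
"Ulanqab","IMNG",2020,4889.84
"Ulanqab","IMNG",2021,4949.58
"Ulanqab","IMNG",2022,5018.42
"Xilin Gol League","IMNG",2018,11506.66
"Xilin Gol League","IMNG",2019,11448.45
"Xilin Gol League","IMNG",2020,11662.44
"Xilin Gol League","IMNG",2021,12157.16
"Xilin Gol League","IMNG",2022,12802.31
"Hinggan League","IMNG",2018,9942.4
"Hinggan League","IMNG",2019,10592.59
"Hinggan League","IMNG",2020,11275.37
"Hinggan League","IMNG",2021,11185.56
"Hinggan League","IMNG",2022,11429.695
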