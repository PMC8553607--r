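"kind","seed","spacing_mm","chi_fcc","chi_hcp","chi_col"
"FCC",101,445.853839535266,1.85421509095887,0.11850167600992,-0.0687678039210209
"FCC",102,450.265600625426,1.58543594794837,0.347982203098354,-0.0604652311610156
"FCC",103,475.947714969516,1.80928947840603,0.0116989645650847,-0.119169126767278
"FCC",104,206.447246018797,1.81756841218952,0.181816025334195,-0.282980287464413
"FCC",105,287.694211956114,1.89470321423541,0.0803390440921292,-0.24208407448204
"FCC",106,560.364520084113,1.24845825350747,0.392634913223063,-0.152689712477643
"FCC",107,237.309703510255,1.97895033864909,0.017347904262477,-0.312999140734031
"FCC",108,538.7476564385,1.47447990613188,0.308031916748553,-0.0844254875321841
"FCC",109,517.087105475366,1.53540242308132,0.229688906879134,-0.104038915338374
"FCC",110,360.576843470335,1.61194174455479,0.420789716131028,-0.239954023211752
"HCP",101,445.853839535266,0.94759191376781,0.561391208748214,-0.205189079673567
"HCP",102,450.265600625426,1.02744869578787,0.414534125734856,-0.272517513741064
"HCP",103,475.947714969516,1.24533639101825,0.436334721293772,-0.250431306874549
"HCP",104,206.447246018797,0.0415000383197728,0.613977252170778,0.0627272857739226
"HCP",105,287.694211956114,0.608342489771513,0.261037959746566,-0.201529175509296
"HCP",106,560.364520084113,0.955360744374373,0.266331452907851,-0.00828181840342437
"HCP",107,237.309703510255,-0.0198519151393691,0.440910355837474,0.0241802178572927
"HCP",108,538.7476564385,1.04817419650745,0.431249711189761,-0.259428086976276
"HCP",109,517.087105475366,1.17362524213308,0.419818560287806,-0.287236872084213
"HCP",110,360.576843470335,-0.0397980295413319,0.992017847313151,-0.495128815454437
"COL",101,445.853839535266,-0.0349046709763858,0.734821285978913,1.33129906002984
"COL",102,450.265600625426,0.0971461104997666,1.12523840480836,1.29848266256334
"COL",103,475.947714969516,NA,NA,1.39577776638076
"COL",104,206.447246018797,-0.343214403392773,0.168242687498604,1.24309649560313
"COL",105,287.694211956114,-0.365544986740339,0.32138045126037,1.39897166183519
"COL",106,560.364520084113,NA,NA,0.964149026215006
"COL",107,237.309703510255,-0.191367755145825,-0.0353654572983828,1.19703630758056
"COL",108,538.7476564385,-0.197151889813447,-0.319785709891372,1.21086187215025
"COL",109,517.087105475366,NA,NA,1.28093525142168
"COL",110,360.576843470335,-0.121299329140382,0.627304518818532,1.24384047693011
"RND",101,445.853839535266,NA,NA,-0.0538890709691863
"RND",102,450.265600625426,NA,NA,0.000772071602245405
"RND",103,475.947714969516,NA,NA,0.0762599490434397
"RND",104,206.447246018797,NA,NA,0.215848200715384
"RND",105,287.694211956114,NA,NA,0.0601356685612445
"RND",106,560.364520084113,NA,NA,-0.13406565435721
"RND",107,237.309703510255,NA,NA,0.106443210625366
"RND",108,538.7476564385,NA,NA,-0.0594750658225838
"RND",109,517.087105475366,NA,NA,-0.0959709971602165
"RND",110,360.576843470335,0.250840540072751,-0.559565601186265,0.0376498936287037
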