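region,year,RS,HC,PG,PD,ES,URB,IND
R01,2005,2.0241631074426385,0.85494218117652754,0.92994228447088922,1.2420087082795124,0.93859326950616195,0.63443962987681835,0.62528386098561162
R01,2006,3.0308586892179896,1.006212046951714,0.82048194844991207,1.2569077894949359,0.84404580454237932,0.61988958453743281,0.62649775321473511
R01,2007,2.2306968707525687,0.90028594248285987,0.90881422240499721,1.3813131210574394,0.97335088829753313,0.64450736089727945,0.54305141231265874
R01,2008,3.3772313683218966,0.85987307756880449,1.0176794764261015,1.0959152114329713,1.0247826686994426,0.60988606195325201,0.51355596337109211
R02,2005,3.2208371318143594,0.85720373376575165,0.99127846154783106,1.2157282124538533,1.0628647906546345,0.57245336561533045,0.52479008443522945
R02,2006,3.093545387314625,0.99052873216053139,0.87997591006516152,1.2480004222256,1.0345440148326244,0.5169757414344831,0.57927511835673007
R02,2007,3.1273588898593809,0.85934507044107034,1.0182947613842068,1.4915029521273895,1.0163795144760919,0.64965873488361547,0.50984382801478068
R02,2008,3.3323135609566159,0.78848437257940807,1.0165443498620934,1.1127846537116668,1.0169587112627843,0.5863476330305023,0.47387252362234528
R03,2005,4.2817414693570131,0.72058824897248741,0.90555937635414874,1.1699488066102908,1.2174792501686376,0.60271196090541224,0.52790699298290955
R03,2006,3.8699667768153123,0.75327184391428703,0.86920357017874561,1.1801667861472973,1.2018525509646993,0.48314489630082175,0.55468306380954513
R03,2007,3.3064717403442314,0.71098492145999104,0.89274629757390378,1.1518270318645225,1.0262679173933935,0.62658227035396463,0.4927621300486878
R03,2008,2.7212677913519578,0.69452246830517483,0.94065419260938421,1.021102548062117,1.0350931956748359,0.58119097309043255,0.44158703810972316
R04,2005,5.3038634377483769,0.79473003709879619,0.8438714600870546,0.95231256749453619,1.0573731914474811,0.53827913662803706,0.52594847579628656
R04,2006,5.0351591197967913,0.73087698333478879,0.73235834118938248,1.0979437960812426,1.0437858553625046,0.5283797878748463,0.49938843227281438
R04,2007,4.8655272214829193,0.73236238665298037,0.66783291163165714,0.87439501004852027,0.98320292217114469,0.66254969344332804,0.47036635724504561
R04,2008,5.388389511777449,0.73989898806294729,0.65235983518897023,0.97422384306538734,1.0028798493870377,0.64543619906635008,0.42912801033230297
R05,2005,1.7359850890581012,1.0045232222584439,0.82551507715592731,0.87220876806896097,0.94402596206335609,0.48790849550715903,0.50366142790342927
R05,2006,1.925549725127399,0.87650766797870572,0.73925316981849498,1.1041775949296626,0.88052530966368581,0.5170526576624791,0.4491128494643355
R05,2007,2.6614183608419912,0.91850247293556309,0.65004527286196545,1.1371492418703055,0.79965851758625972,0.53012197576519526,0.39388080696846889
R05,2008,2.1536427093593731,0.91147464006196366,0.57924311216929381,1.2154261775519006,0.84114906747064833,0.54442695315496537,0.35509450198541043
R06,2005,2.8120464278606905,0.90840647219889148,0.83104773023356182,1.0947020642565235,0.95987930046696934,0.61643137238439571,0.60713808843436678
R06,2006,3.1422540198336972,0.91766803446615508,0.8180678247741543,1.1953384647510727,0.82717741682961532,0.57647034226519456,0.55359923747180051
R06,2007,3.0743480431217418,0.93417355264145363,0.77554222751279378,1.3872830566793106,0.7993476191889286,0.48524959957014313,0.44817295634213777
R06,2008,3.5910057793697576,0.93303882943520344,0.83615799145087277,1.2545992363007283,0.8748467189315835,0.50118760004235829,0.40439359804267871
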