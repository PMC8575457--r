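genotype,sensillum,C1,C2,C3,C4,C5,C6
"Dmel","s1",23.929429074261584,122.46445708313524,62.86426139105501,22.757833353982818,5.114019600631563,-1.5671873686295905
"Dmel","s2",25.209414681650621,117.91347635489366,42.113203489675655,34.954449620933289,1.1861238200269799,-12.858131661950853
"Dmel","s3",18.190116873673226,118.61808746247178,75.61507876826569,14.444118641399497,-2.7922216043122781,4.6403640709116623
"Dmel","s4",9.4995418439404276,143.61363530556463,50.963393430034728,15.768726543739909,6.1124854832456901,24.089158016350368
"Dmel","s5",-4.3395319806335024,120.24825679764909,50.961446181936225,46.336733113352331,22.295796574582397,2.6646611086198977
"Dmel","s6",16.459638125001089,109.75241762338277,63.81743935243108,NaN,1.817380074207307,-5.8003868296432302
"Dsim","s1",10.050541407382681,102.99114083980797,62.034839930003898,NaN,13.648010100745704,-0.1598742452461428
"Dsim","s2",18.091910312802213,110.4232518557951,NaN,5.5609907933978491,17.230304823744483,10.603172544661577
"Dsim","s3",-0.13253093017366879,129.98789106884328,49.389684784228095,NaN,8.5293931463283155,8.753589617877795
"Dsim","s4",2.75302779830586,93.832337145943939,47.155010833176405,22.540800223029244,19.287182362043165,0.53273743704776422
"Dsim","s5",25.831982477367898,134.16507650963041,32.287564741656276,9.750129169624099,-9.8270909990768409,6.1542405684737993
"Dsim","s6",23.215024707845213,109.19141297331775,37.565922107877213,42.060702447850232,36.9330098406964,9.5238401457526667
"Dsec","s1",15.740657817153439,35.215560614423353,63.772239981571488,148.63803648241912,29.038440986702287,10.782980834324142
"Dsec","s2",11.578907242974976,39.62103630390046,54.031188132698098,125.71387768207663,64.207339790280059,7.1634295071116165
"Dsec","s3",6.0081396321833767,32.168318184671534,72.543314461954836,NaN,58.348593119873122,10.438976091800503
"Dsec","s4",-7.1716945824026297,44.733538791051309,73.962281340205678,107.90805464156394,28.748231189179428,26.828768721176452
"Dsec","s5",20.314681857727034,35.443383511096172,79.053459284430346,132.32849424571936,39.051889392953768,5.7601278366587607
"Dsec","s6",10.28358264900239,36.828620079443432,58.357807930905601,95.181454208954833,59.591988213552277,20.973246761082663
"Dyak","s1",-0.28549882480212574,131.15649766366155,53.814020157772077,49.09340069122365,2.9496542476952481,17.138218240964804
"Dyak","s2",12.229065304549673,137.30167995497595,47.234734249384779,30.083573259407174,9.5461937571847688,-18.507086520678484
"Dyak","s3",-10.664860654032395,98.398693297157763,63.021745426806177,19.496316955461914,3.49861784599213,15.821297336387607
"Dyak","s4",21.682660060017334,113.59445967435201,56.955539093277835,39.966603361975835,NaN,-17.10500283404722
"Dyak","s5",17.360990573018565,121.18455805654334,49.808803998147695,41.014636778278494,NaN,6.8575183236193968
"Dyak","s6",8.8671686319654874,99.763343849882929,50.89090344837274,13.212161377794667,15.473378290502431,2.6410655782174102
"Dere","s1",25.510447998249685,87.876956849202742,56.333865896118013,10.374594217516396,10.279551071437947,7.2453789693435926
"Dere","s2",13.11968419369131,106.62894606121021,27.900943187183074,42.527994723375741,14.705792247053084,12.229223037358297
"Dere","s3",-3.6456269821533418,84.898385881711278,68.053722628655748,23.908814487962132,12.958063800065922,31.408958749871005
"Dere","s4",5.8760134918203812,95.369666339837863,46.778550121989021,24.441960253781339,-5.3173838559755566,-1.9129202984788396
"Dere","s5",13.167006176470267,78.432126524402747,46.140898073168614,42.828447873152392,32.520218032319733,-2.5299443183199113
"Dere","s6",6.3081929992835271,127.73879129682459,52.665919477581163,NaN,5.9950129730793913,17.900790591953278
"Dana","s1",7.0623453163253771,119.55544542979881,63.721069987253863,40.696251093342788,15.226536536203623,5.8364625769127949
"Dana","s2",9.6329847943822973,84.585723705231445,34.840768507427939,30.287872764901753,32.402917445059863,NaN
"Dana","s3",28.554636682363697,103.58045939885582,29.473682206904869,40.411738514344123,2.8531633614539462,5.4654461128625123
"Dana","s4",11.02552287139047,89.596442364828874,50.50574732996639,4.7673429943876897,14.663236819580813,13.064499530146588
"Dana","s5",2.0323524037227969,101.45477341738918,43.854156289332643,29.96282251547159,-1.1349280444444219,6.6680910112938321
"Dana","s6",8.8643998603242338,91.745678109572225,53.654696602142394,28.448968373475271,15.178561382584045,20.376786967962445
"Dpse","s1",-3.4371658233855555,84.695066511940723,51.283684041822518,41.445938790360572,1.9734051228185443,27.557894577780466
"Dpse","s2",9.5637007592884107,102.78707439338477,38.495129433328664,44.839805153559219,18.340477043556433,10.477821275619315
"Dpse","s3",23.226052361652787,89.216112624392352,32.386379522367115,47.099433308655044,14.426236438130815,30.646772590749201
"Dpse","s4",12.057707835233714,90.136220008416203,49.188731112017244,NaN,7.3145560367787583,-3.0772379416534132
"Dpse","s5",24.214019667481857,74.052969101314176,49.276638528409663,32.820880357356131,0.1478969780195456,10.638980512646549
"Dpse","s6",-12.720010690880692,98.118783936485613,50.707744438146122,55.162140349682154,10.585317935881745,-10.942449408914328
"Dwil","s1",14.314928326850653,26.75713082776376,62.89091786759866,108.65421124086224,NaN,20.357170375445811
"Dwil","s2",-0.74171199760130335,42.068036515708478,62.323214838399679,98.980195855008617,8.4787585826840548,25.017633609555663
"Dwil","s3",-5.6969257169615304,30.95390515202822,56.05822419631798,88.528319694516867,NaN,16.462673620213081
"Dwil","s4",17.542424069902523,37.975360014613827,48.201407700464941,105.09471669917187,NaN,8.9246506742316214
"Dwil","s5",-14.487868922602956,23.046731114494044,56.360962446927502,130.17659385890232,30.438313148166124,0.057428733221629003
"Dwil","s6",16.237102736791456,42.389124090962525,58.063807058015591,107.88198588159601,42.002742975321844,-4.2427271332435659
"Dmoj","s1",9.5282724767635543,40.193163062055845,69.610887444529382,105.97894017077688,21.214638172560342,14.239881443066146
"Dmoj","s2",3.1582335570446198,26.171394086575194,55.189705043315179,110.27419146318378,33.961548342985722,26.405540567927794
"Dmoj","s3",-5.3032555808600996,9.3051475337481939,62.022910627864277,105.3321491683066,53.985979916730926,42.625612800829984
"Dmoj","s4",15.340493237660461,31.731781100341887,40.388129502487438,100.61615313294273,39.759667564929067,35.656144841344236
"Dmoj","s5",1.6984334756071764,45.193747331351133,58.113911635286811,94.637971621661265,60.340575557907201,10.499444213861814
"Dmoj","s6",4.3538355052232367,20.545475542927967,60.524938585680275,80.983338448661726,39.615548761606846,11.732602718241694
"Dvir","s1",5.5302710336694361,27.982872175435876,51.046788068560758,92.027933343425914,27.944490555491264,-2.8149976111079553
"Dvir","s2",4.884327683728146,39.267193586213509,61.119056837481189,121.88680983107568,45.528410399432126,-9.6923362094054042
"Dvir","s3",-5.4119489880650953,23.714441134341296,75.388724197549095,107.05036931656468,42.906400888467324,-5.7003502675790223
"Dvir","s4",7.7758736804851365,31.638583356877952,55.811533735040392,101.43320107846984,29.314385248673105,1.9283329271336669
"Dvir","s5",21.744251816458029,37.660164203799653,68.737012150947692,105.67257531788768,42.471090582743123,16.39149207663916
"Dvir","s6",-9.3351650069941705,38.81130116775401,26.018458866361733,119.86301338008415,40.051957718304493,9.1977814770326134
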