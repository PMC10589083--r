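farm_id,food_code,quantity_kg,quantity_sold_kg,sales_value_usd
f00001,catla,477.5729056379733,304.080446456236,436.98316401562937
f00001,tilapia,292.3960461193537,289.7674702496817,315.2215615763707
f00001,pangas,529.1804003893019,525.3538086216619,693.5660958285197
f00001,gulsha,273.47434339055667,0,0
f00001,koi,430.9530872474846,285.3648845598366,340.20923622445906
f00001,pool_barb,51.66705444706616,46.70457450857735,72.8548211469659
f00001,tengra,43.65510509039741,36.55646616205879,49.71994529910006
f00001,mola,54.057181550361356,40.57359367991664,63.5149216874753
f00002,mrigal,127.3954512284138,116.74229530562498,177.8132268508525
f00002,catla,387.73396766003833,232.43885236862099,325.1690956046227
f00002,rohu,289.8074386797978,268.1436652903522,236.99801719988378
f00002,koi,176.51462858677843,136.49025581588762,177.0053798622687
f00002,pangas,544.0240151140652,347.5514740538558,469.5143132836368
f00002,silver_barb,91.97732805912226,82.43782066645974,69.83773389510647
f00002,pool_barb,35.460965837791,35.22578989612131,49.55535985577452
f00002,taki,56.48539234770263,47.63693792955186,78.02596509504721
f00003,catla,460.18906462815534,192.69396345231857,275.01448095054747
f00003,mrigal,170.3775145214606,164.3728267057407,238.50627248966435
f00003,silver_carp,193.67667980126222,145.55339620640893,177.54699034987257
f00003,rohu,292.17034311802695,265.0681436419874,235.74353347592006
f00003,silver_barb,164.5622791484724,95.52896342667049,84.964044292039
f00003,koi,109.8464311229953,0,0
f00004,rohu,57.439482130666,47.63918883763427,45.182246179051454
f00004,catla,44.739198526223255,43.092703791738856,64.07447842264271
f00004,silver_barb,77.77923593693433,52.456170968981695,45.02509505835428
f00004,koi,196.6292733967045,159.17329718207142,192.7035543521374
f00004,mola,8.654703062780802,0,0
f00004,tengra,8.695155024302029,0,0
f00004,mango,69.71987105263403,65.75427222343023,35.723735467761045
f00004,coconut,78.30130044974591,57.67175964238743,29.191694295475465
f00004,betel_nut,17.882763313325462,16.37798235073513,20.911107645202108
f00004,eggplant,33.286032252496135,19.932895254130273,10.1195651211446
f00005,catla,110.09326508567541,69.96087401823753,101.13470501878061
f00005,mrigal,236.47711762066876,0,0
f00005,gulsha,113.13525811104364,0,0
f00005,koi,256.37370661004337,197.97475854171518,233.33409150643223
f00005,taki,17.400044703515384,10.226530540573682,14.91759615029024
f00005,tengra,12.017982292577011,11.693723329452215,16.311353817378006
f00005,pool_barb,58.044233095900076,43.869700672165976,65.87379983550642
f00005,mola,18.697152163516037,17.816557537705886,25.76044134872488
f00005,golda,76.19432509565227,49.22002770459256,201.54883282307662
f00005,rice,1788.4614968980839,0,0
f00006,mrigal,130.660130753232,107.97150547223686,170.29054224742714
f00006,rohu,420.691867094843,337.68191327540114,291.9958073846837
f00006,tilapia,315.06466294086874,175.78143003951809,173.70807555591236
f00006,silver_barb,209.1287352152579,196.6655073958379,161.65652124836123
f00006,pangas,360.4427342651906,288.15556846807414,362.1272163202208
f00006,koi,143.9972766017046,130.14107030987287,171.3518108327527
f00006,tengra,42.01999662517301,30.915054836649837,40.86231962033217
f00006,pool_barb,302.17028628746147,285.326925291033,447.21191468957585
f00006,mola,61.07030949911443,49.37707159169138,72.81520235063238
f00006,taki,21.859619790429253,19.00166354831627,29.659890833174344
f00006,golda,101.62591794258651,99.3481196436354,361.90481384371793
f00006,rice,3104.4215223790416,1188.5307155078524,452.7605340127443
f00006,red_amaranth,976.9368479412949,0,0
f00006,mustard_seed,192.32774872003083,77.61989151094888,103.92846846654635
f00006,taro,1042.392778225574,865.2550860398362,255.89479481128637
f00006,banana,594.1906582798181,313.9711517858963,136.0132507118237
f00007,mrigal,554.6444274792441,478.0646260244941,713.5124735090722
f00007,silver_carp,419.69959645015945,0,0
f00007,catla,251.6564687649175,151.28392357101762,228.83443792245905
f00007,rohu,275.62537260375433,171.6335240326268,147.1697772679335
f00007,pangas,633.6879114093322,469.05141810748364,590.3867213927966
f00007,tilapia,429.1263670358485,364.15619358105363,375.02227244861984
f00007,koi,143.17777366825777,121.85208323724794,148.50778157589144
f00007,pool_barb,43.405911309975835,31.64173221358383,50.310519523209486
f00007,taki,31.052105728018443,24.94777043282932,38.15501823120763
f00007,tengra,54.32149989091717,33.39597440217502,49.26094184715741
f00007,golda,164.42453919789526,76.34981644537389,288.20455775600254
f00007,harina,215.77573038812116,206.6023343999647,837.92893722234
f00007,bagda,258.2924544928046,165.76383501760375,534.3539722790257
f00008,mrigal,1120.19324730256,961.3835277358675,1565.8129058616307
f00008,rohu,750.0097999366633,610.2014481500573,545.969514838724
f00008,catla,323.73183373386615,200.07823373161582,270.313919133008
f00008,silver_carp,252.74483258761668,109.49457886481183,134.04537417089566
f00008,taki,25.184571149723503,23.760652657442467,33.13748674938937
f00008,mola,63.461831566999116,53.90241280217136,88.54355291176424
f00008,pool_barb,40.90694417431643,28.402965495887678,41.77944990765967
f00008,golda,778.3242900027304,560.9306373843548,2150.596519705477
f00008,harina,118.25538819163963,0,0
f00008,bagda,97.52455666124047,0,0
f00009,silver_carp,219.1985105144193,189.85339216339742,227.44220104447714
f00009,mrigal,168.36667887230735,91.98318005993528,136.60958318212178
f00009,pangas,213.83327026909313,0,0
f00009,gulsha,36.48112083939382,25.45908305726596,25.296348322990877
f00009,koi,56.5371130993631,39.567532322238044,54.20304328310432
f00009,mola,27.547693620262013,21.01898628303277,33.80029442077143
f00009,taki,33.73947762423138,25.37661679852628,36.04233996691089
f00009,pool_barb,33.78568399285635,28.301441929167073,42.9094270654021
f00009,golda,64.13275935102651,25.74629645406731,102.33414615643463
f00009,harina,137.9663604565547,93.44251129083837,373.87489778498247
f00009,rice,1541.9003555472684,953.7757900109908,358.8051394522199
f00009,bitter_gourd,152.42475205117714,119.26807428863857,46.80093537884569
f00009,banana,111.29862678362234,87.72754339060931,37.96235869756816
f00010,rohu,278.67407847360846,136.53251366268609,122.99266495769167
f00010,koi,231.10507027078313,209.14543215149504,287.27001705987766
f00010,gulsha,265.4048054753903,0,0
f00010,pangas,307.96823707970526,259.6920654207866,342.8997246368057
f00010,tengra,20.508712193986995,7.629373695013247,12.375929641024168
f00010,taki,53.19116421284478,48.96281301918926,73.40900113365997
f00010,harina,133.6793078290352,127.2113450134825,528.0780358528797
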