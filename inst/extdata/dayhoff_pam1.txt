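   A R N D C Q E G H I L K M F P S T W Y V
A 9.8678549505e-01 1.1046521534e-04 3.9402397963e-04 5.5686285550e-04 1.1989665337e-04 3.3709070693e-04 9.6589186653e-04 2.0983555489e-03 7.7556448017e-05 2.3885884843e-04 3.4725521415e-04 2.1016643973e-04 1.0513268433e-04 7.1286168143e-05 1.2496759876e-03 2.7966788481e-03 2.1377274813e-03 1.4055172048e-07 7.1278440809e-05 1.3261610065e-03
R 2.3529490556e-04 9.9139493592e-01 1.3163907531e-04 1.7298753296e-06 7.6508557320e-05 9.2831610733e-04 7.8659285840e-06 8.0859419886e-05 7.9669098676e-04 2.3314895925e-04 1.2811052124e-04 3.6848646781e-03 1.3158033930e-04 5.5397371750e-05 5.1661478971e-04 1.0553332627e-03 1.5377797244e-04 2.0862965386e-04 2.4052644416e-05 1.5464902988e-04
N 8.4908308451e-04 1.3317581956e-04 9.8229992594e-01 4.1551317316e-03 1.1838245926e-06 3.9159309002e-04 7.3218859775e-04 1.2174505052e-03 1.7662776795e-03 2.7968543485e-04 2.8701941775e-04 2.5171619136e-03 2.4688345680e-06 5.5897015153e-05 2.1305403125e-04 3.3745912217e-03 1.3213745722e-03 2.3946007805e-05 2.8008965191e-04 9.8701621601e-05
D 1.0351124341e-03 1.5096181192e-06 3.5842354961e-03 9.8598994606e-01 3.0012384733e-07 5.1218062121e-04 5.6032675366e-03 1.0962278137e-03 2.8847994074e-04 8.8524255398e-05 1.5425005770e-06 5.6956128452e-04 4.4162252816e-07 3.0535901947e-07 6.7461712873e-05 6.5851126346e-04 3.8465203491e-04 7.3128626295e-08 8.6125878235e-07 1.1680593834e-04
C 3.1207013558e-04 9.3490650314e-05 1.4298977095e-06 4.2024869965e-07 9.9734315553e-01 3.9056421863e-07 4.8490832200e-07 9.8051300341e-05 9.3280124169e-05 1.6079365798e-04 6.2944314004e-07 7.7251927158e-07 1.8136893291e-07 5.9279102986e-07 9.6253796836e-05 1.1043668316e-03 9.4821554255e-05 6.3506007948e-08 2.8451173375e-04 3.1423943986e-04
Q 7.6773498949e-04 9.9259814545e-04 4.1387771051e-04 6.2755012619e-04 3.4175262461e-07 9.8770737123e-01 3.4836377283e-03 2.4794265482e-04 2.0057272311e-03 6.6900309305e-05 6.1577388822e-04 1.2169289964e-03 1.6590324078e-04 5.7711554563e-07 7.6561046264e-04 3.8759071505e-04 3.0793277980e-04 1.6753957098e-07 6.9264264046e-07 2.2514074490e-04
E 1.6990765325e-03 6.4960214577e-06 5.9769532373e-04 5.3025712897e-03 3.2771696287e-07 2.6906230829e-03 9.8651470023e-01 7.1271764507e-04 1.4638622981e-04 2.2201699511e-04 9.4422195608e-05 6.6188631506e-04 4.4055927306e-05 3.9106340473e-07 2.5722282927e-04 5.4564008141e-04 2.0048494525e-04 3.5482428472e-08 6.5071136532e-05 2.3817895179e-04
G 2.0631903570e-03 3.7325347707e-05 5.5549991903e-04 5.7985814658e-04 3.7039782734e-05 1.0704020065e-04 3.9837612242e-04 9.9352152316e-01 3.4154883184e-05 1.1871619805e-06 6.0092129362e-05 2.1669127347e-04 2.5049441345e-05 5.9243507342e-05 1.7271965433e-04 1.6055139550e-03 1.7856518873e-04 7.7769454845e-08 3.5216444943e-07 3.4649983075e-04
H 2.0100126856e-04 9.6935713375e-04 2.1242827990e-03 4.0221404552e-04 9.2880566257e-05 2.2823813203e-03 2.1567344764e-04 9.0027143456e-05 9.9128835347e-01 2.6769610872e-05 3.7246338855e-04 2.1278773176e-04 5.5251666810e-07 1.8925922308e-04 4.7164975515e-04 2.4517981522e-04 1.2965286356e-04 2.8180620138e-05 3.7568207463e-04 2.8165120182e-04
I 5.6419928663e-04 2.5854592608e-04 3.0657272412e-04 1.1249007480e-04 1.4592004846e-04 6.9383270956e-05 2.9812128634e-04 2.8519437568e-06 2.4397895633e-05 9.8731739357e-01 2.1677492566e-03 3.6704352172e-04 4.8884917102e-04 7.6918614655e-04 6.1649496693e-05 1.6855793123e-04 1.1076250319e-03 1.2387836923e-07 1.1037119860e-04 5.6589683401e-03
L 3.5445604981e-04 6.1391950991e-05 1.3595568142e-04 8.4703172610e-07 2.4684536324e-07 2.7597537512e-04 5.4790249756e-05 6.2383679921e-05 1.4669534070e-04 9.3676674531e-04 9.9471607547e-01 1.4479473429e-04 7.6676105810e-04 6.1823214680e-04 1.6096809746e-04 1.1828384247e-04 1.9246155885e-04 4.7854055385e-05 8.3666810143e-05 1.1213932767e-03
K 2.2751884141e-04 1.8727877637e-03 1.2645546891e-03 3.3170741940e-04 3.2130551052e-07 5.7843516262e-04 4.0733616442e-04 2.3858064070e-04 8.8883203280e-05 1.6822105989e-04 1.5356532062e-04 9.9259438242e-01 3.5331050787e-04 4.2633429725e-07 1.6674886799e-04 6.6213505528e-04 7.8639383508e-04 2.4401522442e-07 3.8760925114e-05 6.5686469065e-05
M 6.2088357537e-04 3.6481815216e-04 6.7660760016e-06 1.4030862292e-06 4.1151926117e-07 4.3019239991e-04 1.4790822744e-04 1.5045625273e-04 1.2590324238e-06 1.2222389021e-03 4.4362789695e-03 1.9274138341e-03 9.8756266209e-01 3.6254605195e-04 8.6642838404e-05 4.2660354723e-04 6.0183478952e-04 1.7612242375e-07 8.2586155326e-07 1.6486786750e-03
F 1.5616388343e-04 5.6974104749e-05 5.6824603155e-05 3.5987096351e-07 4.9892102317e-07 5.5510296686e-07 4.8701021913e-07 1.3199451053e-04 1.5997477023e-04 7.1337122100e-04 1.3268239303e-03 8.6272344644e-07 1.3448259842e-04 9.9458834379e-01 5.5595830237e-05 3.1593378667e-04 7.6581007940e-05 7.9107833336e-05 2.0651183134e-03 7.9946192685e-05
P 2.1483922607e-03 4.1696155009e-04 1.6997238736e-04 6.2392766492e-05 6.3575366916e-05 5.7790900253e-04 2.5138608393e-04 3.0199356767e-04 3.1286348597e-04 4.4869836919e-05 2.7110800897e-04 2.6480430926e-04 2.5221819159e-05 4.3629782166e-05 9.9260055643e-01 1.6802228665e-03 4.5504656257e-04 1.2431948313e-07 3.7219359281e-07 3.0859740320e-04
S 3.5021090015e-03 6.2042559723e-04 1.9610140172e-03 4.4361987354e-04 5.3131890309e-04 2.1310609547e-04 3.8842653797e-04 2.0447533320e-03 1.1846522598e-04 8.9360389949e-05 1.4511050982e-04 7.6591335526e-04 9.0456359605e-05 1.8059586593e-04 1.2238770696e-03 9.8414521758e-01 3.1617395024e-03 7.7643995206e-05 1.0100346329e-04 1.9584332543e-04
T 3.1815411544e-03 1.0744652019e-04 9.1260661926e-04 3.0797393633e-04 5.4218453540e-05 2.0122251531e-04 1.6962214031e-04 2.7028489808e-04 7.4453724970e-05 6.9788966770e-04 2.8061803967e-04 1.0811135362e-03 1.5166664360e-04 5.2027259878e-05 3.9393529075e-04 3.7577183793e-03 9.8717716955e-01 1.8347989601e-07 1.2441648605e-04 1.0038917032e-03
W 1.1669382266e-06 8.1320634282e-04 9.2260814520e-05 3.2663283506e-07 2.0257290928e-07 6.1075150447e-07 1.6747138194e-07 6.5669019746e-07 9.0277881437e-05 4.3542762794e-07 3.8923943258e-04 1.8714344665e-06 2.4760187893e-07 2.9981672836e-04 6.0039178624e-07 5.1479285825e-04 1.0235639481e-06 9.9761159000e-01 1.8112835440e-04 3.7810990381e-07
Y 2.0759047708e-04 3.2887062682e-05 3.7854608925e-04 1.3494090669e-06 3.1834957132e-04 8.8571480850e-07 1.0773410190e-04 1.0431206109e-06 4.2217141278e-04 1.3608610882e-04 2.3872001315e-04 1.0427720200e-04 4.0727154349e-07 2.7454835393e-03 6.3052451148e-07 2.3490834220e-04 2.4346804139e-04 6.3536600853e-05 9.9458206385e-01 1.7986154449e-04
V 1.7853522979e-03 9.7743501318e-05 6.1662968024e-05 8.4596680084e-05 1.6253362295e-04 1.3308135598e-04 1.8228318987e-04 4.7442818076e-04 1.4630473906e-04 3.2253268981e-03 1.4790130400e-03 8.1686368604e-05 3.7582985401e-04 4.9130380659e-05 2.4165945169e-04 2.1054715927e-04 9.0809091891e-04 6.1310382437e-08 8.3141289363e-05 9.9021752679e-01
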