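province,internet_penetration,social_networking_msm,msm_n,pct_adult_men
Guangdong,74.0,516113,697450,1.81
Sichuan,43.6,248679,570365,2.07
Jiangsu,56.6,317627,561178,1.97
Henan,43.4,208489,480389,1.53
Shandong,52.9,249935,472467,1.37
Zhejiang,65.6,268375,409108,1.99
Hunan,44.4,174478,392968,1.69
Beijing,77.8,274233,352485,4.38
Hebei,53.3,184049,345308,1.34
Hubei,51.4,168538,327895,1.55
Anhui,44.3,131758,297422,1.46
Liaoning,62.6,176804,282435,1.70
Shanghai,74.1,204844,276443,2.97
Shaanxi,52.4,131830,251584,1.82
Guangxi,46.1,112368,243748,1.57
Chongqing,51.6,124544,241364,2.47
Yunnan,39.9,94461,236744,1.48
Heilongjiang,48.1,111801,232435,1.57
Jiangxi,44.6,96776,216987,1.43
Fujian,69.7,148229,212667,1.55
Shanxi,55.5,95710,172450,1.35
Jilin,50.9,87452,171811,1.62
Guizhou,43.2,71265,164965,1.50
Inner Mongolia,52.2,71022,136057,1.42
Gansu,42.4,57249,135021,1.52
Tianjin,64.6,77784,120409,2.23
Xinjiang,54.9,59678,108703,1.41
Hainan,51.6,39051,75680,2.46
Ningxia,50.7,22611,44598,2.06
Qinghai,54.5,17610,32312,1.64
Tibet,46.1,11565,25087,2.49
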