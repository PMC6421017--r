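table,patient,method,tp,fp,tn,fn,sensitivity,specificity,accuracy,dice,jaccard
phantom,1,T1c,593,191,14609,0,1,0.987,0.9875,0.8612,0.7563
phantom,1,Flair,592,285,14515,1,0.9983,0.9807,0.9814,0.8054,0.6742
phantom,1,Thermal,556,5,14795,37,0.9376,0.9996,0.9972,0.9636,0.9297
phantom,2,T1c,1160,287,18241,0,1,0.9845,0.9854,0.8899,0.8016
phantom,2,Flair,1138,369,18159,22,0.981,0.98,0.9801,0.8533,0.7442
phantom,2,Thermal,1112,37,18491,48,0.9586,0.998,0.9956,0.9631,0.9289
phantom,3,T1c,1593,105,18116,28,0.9827,0.9942,0.9932,0.9599,0.9229
phantom,3,Flair,1598,431,17790,23,0.9858,0.9763,0.9771,0.8756,0.7787
phantom,3,Thermal,1547,7,18214,74,0.9543,0.9996,0.9959,0.9744,0.9502
phantom,4,T1c,2224,109,17545,204,0.9159,0.9938,0.9844,0.9342,0.8766
phantom,4,Flair,2428,418,17236,0,1,0.9763,0.9791,0.9207,0.8531
phantom,4,Thermal,2375,25,17629,53,0.9781,0.9985,0.9961,0.9838,0.9682
perfusion,1,Thermal wb=0.001,549,3,14797,44,0.9258,0.9997,0.9969,0.9589,0.9211
perfusion,1,Thermal wb=0.0016,556,5,14795,37,0.9376,0.9996,0.9972,0.9636,0.9297
perfusion,1,Thermal wb=0.002,559,5,14795,34,0.9426,0.9996,0.9974,0.9662,0.9347
perfusion,2,Thermal wb=0.001,1099,29,18499,61,0.9474,0.9984,0.9954,0.9606,0.9243
perfusion,2,Thermal wb=0.0016,1112,37,18491,48,0.9586,0.998,0.9956,0.9631,0.9289
perfusion,2,Thermal wb=0.002,1118,47,18481,42,0.9637,0.9974,0.9954,0.9617,0.9262
perfusion,3,Thermal wb=0.001,1538,1,18220,83,0.9487,0.9999,0.9957,0.9734,0.9482
perfusion,3,Thermal wb=0.0016,1547,7,18214,74,0.9543,0.9996,0.9959,0.9744,0.9502
perfusion,3,Thermal wb=0.002,1558,14,18207,63,0.9611,0.9992,0.9961,0.9758,0.9529
perfusion,4,Thermal wb=0.001,2330,17,17637,98,0.9596,0.999,0.9942,0.9759,0.9529
perfusion,4,Thermal wb=0.0016,2375,25,17629,53,0.9781,0.9985,0.9961,0.9838,0.9682
perfusion,4,Thermal wb=0.002,2387,31,17623,41,0.9831,0.9982,0.9964,0.9851,0.9707
hgg,1,Flair,1102,178,17090,66,0.9434,0.9896,0.9867,0.9,0.818
hgg,1,Thermal,1142,18,17250,26,0.9777,0.9989,0.9976,0.9811,0.9629
hgg,2,Flair,1067,165,15176,2,0.9981,0.9892,0.9898,0.9274,0.8646
hgg,2,Thermal,1038,18,15323,31,0.971,0.9988,0.997,0.9769,0.9549
hgg,3,Flair,2891,498,14358,4,0.9986,0.9664,0.9717,0.9201,0.852
hgg,3,Thermal,2767,41,14815,128,0.9557,0.9972,0.9904,0.9703,0.9424
hgg,4,Flair,1678,342,9386,4,0.9976,0.9648,0.9696,0.9065,0.829
hgg,4,Thermal,1561,44,9684,121,0.928,0.9954,0.9855,0.9498,0.9044
hgg,5,Flair,1810,191,17340,69,0.9632,0.9891,0.9866,0.9329,0.8743
hgg,5,Thermal,1803,123,17408,76,0.9595,0.9929,0.9897,0.9477,0.9005
hgg,6,Flair,1982,628,16415,1,0.9994,0.9631,0.9669,0.863,0.759
hgg,6,Thermal,1916,32,17011,67,0.9662,0.9981,0.9947,0.9748,0.9508
lgg,1,Flair,2831,371,16731,106,0.9639,0.9783,0.9761,0.9223,0.8558
lgg,1,Thermal,2803,71,17031,134,0.9543,0.9958,0.9897,0.9647,0.9318
lgg,2,Flair,1378,331,13666,26,0.9814,0.9763,0.9768,0.8853,0.7942
lgg,2,Thermal,1307,34,13963,97,0.9309,0.9975,0.9914,0.9522,0.9089
lgg,3,Flair,1274,413,17336,10,0.9922,0.9767,0.9777,0.8576,0.7507
lgg,3,Thermal,1236,8,17741,48,0.9626,0.9995,0.997,0.9778,0.9566
lgg,4,Flair,1762,560,18243,1,0.9994,0.9702,0.9727,0.8626,0.7585
lgg,4,Thermal,1660,33,18770,103,0.9415,0.9982,0.9933,0.9606,0.9242
lgg,5,Flair,2015,807,13191,0,1,0.9423,0.9496,0.8331,0.714
lgg,5,Thermal,1901,12,13986,114,0.9434,0.9991,0.9921,0.9679,0.9378
lgg,6,Flair,1383,644,13522,0,1,0.9545,0.9585,0.8111,0.6822
lgg,6,Thermal,1271,20,14146,112,0.91901,0.9985,0.9915,0.9506,0.9059
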