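zone_id,sum_dn,odr
Suzhou,373261,18.076
Tianjin,349408,17.923
Beijing,348231,17.915
Shanghai,334746,17.819
Chongqing,300330,17.538
Harbin,265159,17.182
Guangzhou,256275,17.078
Tangshan,254191,17.053
Weifang,249205,16.990
Ningbo,232518,16.765
Nantong,230225,16.731
Chengdu,223101,16.624
Yantai,218269,16.548
Qingdao,214348,16.483
Linyi,211939,16.443
Quanzhou,210609,16.420
Hangzhou,208367,16.381
Cangzhou,200063,16.230
Changchun,197844,16.188
Baoding,189983,16.032
Yancheng,188884,16.009
Ordos,187564,15.981
Wuxi,186016,15.948
Yulin,180977,15.838
Nanjing,180621,15.830
Zhengzhou,176195,15.728
Shijiazhuang,174421,15.686
Jinan,173470,15.663
Shenyang,170688,15.595
Handan,170627,15.593
Jining,170199,15.582
Wuhan,170083,15.580
Foshan,169524,15.566
Huizhou,167721,15.520
Xuzhou,166657,15.492
Dalian,157692,15.249
Fuzhou,156327,15.210
Kunming,155533,15.187
Nanyang,152235,15.089
Langfang,150066,15.022
Daqing,149761,15.013
Suihua,146411,14.907
Wenzhou,145549,14.879
Zhangzhou,145227,14.868
Jiaxing,145137,14.865
Xi'an,144576,14.847
Dongguan,140280,14.702
Yan'an,140273,14.701
Jinhua,139724,14.682
Taizhou A,139068,14.659
Qiqihar,138330,14.633
Xingtai,136448,14.566
Yangzhou,136258,14.559
Binzhou,136179,14.556
Taizhou B,135832,14.543
Hulunbeir,135027,14.513
Luliang,133380,14.452
Changzhou,133260,14.447
Jiangmen,132327,14.412
Hefei,132237,14.409
Heze,131710,14.388
Dezhou,130769,14.352
Shaoxing,126333,14.174
Changsha,123222,14.043
Dongying,115762,13.706
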