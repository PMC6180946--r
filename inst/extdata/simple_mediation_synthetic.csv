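"x","m","y"
-0.485395733,-1.234048011,-1.950301174
-0.6258011834,-1.087407756,-2.98148869
-0.8733806003,-1.570733668,-3.954251746
1.430260961,0.283332787,3.972585075
-1.137137236,0.9712311156,-0.0509854149
0.8438926641,-2.932900047,-5.652855406
-1.374044027,-1.868282251,-4.37125071
-1.711736799,-2.038450422,-5.663879437
-0.131253901,0.870260504,0.82906522
1.264249883,-1.645837506,-1.92852473
0.3326090352,-1.475311793,-1.981376972
0.3838497138,0.6545248256,2.088702299
2.994234819,3.059655076,9.089335523
-0.7557734051,0.5202644942,0.4245086418
-0.7713405445,0.1938178075,-0.2134230098
-0.9433647239,-0.4120672465,-1.619236508
-1.087963605,-1.567083439,-5.894914075
-0.07832941303,1.229933133,2.705851594
1.470229889,2.182318584,6.055188357
-0.009476510172,-0.2442692677,0.08776558589
-0.2634230856,-0.7981654413,-0.4854951598
1.358096324,1.975720147,3.883362338
1.566772355,1.615453132,4.91269963
0.6868215751,0.3130821137,0.1847644204
1.171593003,1.540778334,3.845047547
-0.3615253129,1.101776688,1.721292408
0.06399807981,1.425034753,1.832306628
1.419336165,1.477770991,3.825556256
2.348215766,2.378533796,7.669415184
-0.5679845113,1.617995678,2.023994542
-0.3437018738,-0.4935951323,-0.7796880472
-0.8617392774,-0.4576392265,-2.464867786
1.974617518,1.448394185,4.865310504
-0.5415427535,0.4009949695,-1.228670544
0.2703673396,0.4208809918,1.002129481
-0.5531603793,-1.128452883,-4.723038175
-0.8669114068,-1.477782652,-4.047965753
1.169304423,0.3113913641,2.063425255
-0.6660014425,-0.4269619706,-0.4805135737
-0.07928017966,-1.128254432,-1.397259371
1.043408333,0.6668237911,2.931017386
-1.510667326,-0.03557358048,-1.413014747
-0.4395987404,-0.3538345287,-0.9444437806
0.8744827084,1.556054799,3.84229261
0.6162617137,0.2520105702,0.4138646531
1.460929221,1.885454072,5.490287321
-0.2551830293,-1.443974394,-4.094532079
-0.01628797426,-0.8961554271,-2.085236991
0.2309186313,-1.750336514,-2.949290685
-0.657366729,0.2772655833,-1.765055465
0.1654169747,-0.1237124694,0.747793732
1.447205572,0.6237852047,3.367934523
0.4559924539,0.1535545303,-0.3390804788
-0.1810097882,0.2120950504,-0.6744870013
-0.8888809213,0.7434672263,-0.8946490587
0.3263153598,0.9540945456,1.705232927
0.2371458752,2.009831319,4.631492451
-0.2607233023,-2.127245129,-5.105744611
0.8818413957,0.6265572088,3.102829875
0.1426338011,0.04578339636,3.560326697
0.5026849437,0.6584851509,2.688930448
-0.9787328149,-2.061464465,-4.529509912
-0.6900977162,-1.077722272,-3.442730277
-0.4652982951,-1.149413533,-3.16957567
1.761452726,0.8670036136,2.209072974
-0.01432256088,-0.7109860653,-0.676749518
2.296422339,1.831167099,4.462406606
-0.8748411512,-0.6009455093,-1.797934529
0.1286312373,-1.307539595,-1.809283567
0.8857633182,3.157780103,6.936604526
1.170624322,1.836349174,5.143676902
-0.471702172,-0.3359510025,0.2552609136
-0.1956168979,-0.2565412282,-1.168984193
-0.61773956,-0.2869953514,-0.6375762329
-0.2068765995,-0.6040750433,-1.945656357
-0.05339762311,1.190387707,4.41081004
0.5999010085,0.9868269096,2.371751256
0.1831552752,1.152878537,1.460780775
0.2516493724,0.6632320199,2.233836901
-1.180221217,-1.487404799,-4.20878716
0.7077715951,0.9680911546,2.362054975
0.5598892886,-1.018776663,-1.432755157
-2.205286325,-1.537406936,-3.33211503
0.2441078724,-0.436509964,-1.239856944
1.292628998,0.4954674106,3.358770298
-1.465522537,-1.384950015,-5.630842031
0.6455339335,0.2936463478,0.5301044217
-1.635077284,-1.241973,-2.855336819
-0.8384101055,0.295222388,-1.896783751
0.3304122803,-0.132551214,0.6140556497
1.55614853,-0.1232705056,0.08375296008
0.1867804475,2.292224132,6.288071626
2.233287558,2.288411571,7.984371333
0.6077297288,0.9969571801,2.759064972
0.5806291772,-0.1470114649,2.246010355
-0.5116400655,0.9512984196,0.8665817394
-0.1644188696,-0.35129807,-0.5967431586
-1.10922638,-1.367699075,-4.269642808
0.1122479237,-1.212368352,-1.302126732
0.6196387278,0.9308752999,1.861021547
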