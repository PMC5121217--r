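time_d,location,species,value,unit
18,broth,acetate,9.48464546574736,gCOD_L
18,broth,n-butyrate,3.9032175844967587,gCOD_L
18,broth,n-caproate,1.2248328850731987,gCOD_L
18,broth,n-caprylate,0.3690273796570665,gCOD_L
18,extract_solution,n-caproate,1.544732134131109,gCOD
18,extract_solution,n-caprylate,0.45383930053026345,gCOD
20,broth,acetate,8.852726723628157,gCOD_L
20,broth,n-butyrate,4.46393871287341,gCOD_L
20,broth,n-caproate,1.2611086655209842,gCOD_L
20,broth,n-caprylate,0.3720665909233527,gCOD_L
20,extract_solution,n-caproate,4.3930873867695865,gCOD
20,extract_solution,n-caprylate,1.3311778595570192,gCOD
22,broth,acetate,9.232062242510839,gCOD_L
22,broth,n-butyrate,4.682504867008432,gCOD_L
22,broth,n-caproate,1.282318211341457,gCOD_L
22,broth,n-caprylate,0.3729611206989134,gCOD_L
22,extract_solution,n-caproate,7.388249160275663,gCOD
22,extract_solution,n-caprylate,2.2620913746878393,gCOD
24,broth,acetate,8.739169338681052,gCOD_L
24,broth,n-butyrate,4.6390366254790365,gCOD_L
24,broth,n-caproate,1.2273372625293675,gCOD_L
24,broth,n-caprylate,0.3649016563946955,gCOD_L
24,extract_solution,n-caproate,11.615857756710254,gCOD
24,extract_solution,n-caprylate,3.280733155157185,gCOD
26,broth,acetate,8.749258784443342,gCOD_L
26,broth,n-butyrate,4.758032085636211,gCOD_L
26,broth,n-caproate,1.330752319288231,gCOD_L
26,broth,n-caprylate,0.3746738426925145,gCOD_L
26,extract_solution,n-caproate,13.926113938101407,gCOD
26,extract_solution,n-caprylate,3.94311283207554,gCOD
28,broth,acetate,8.284786867531892,gCOD_L
28,broth,n-butyrate,4.277311185964815,gCOD_L
28,broth,n-caproate,1.1609447152081906,gCOD_L
28,broth,n-caprylate,0.41425762846383457,gCOD_L
28,extract_solution,n-caproate,17.113902153582874,gCOD
28,extract_solution,n-caprylate,5.222530150312255,gCOD
30,broth,acetate,8.850694235101116,gCOD_L
30,broth,n-butyrate,4.319940937186324,gCOD_L
30,broth,n-caproate,1.1001436419945643,gCOD_L
30,broth,n-caprylate,0.3690930500183445,gCOD_L
30,extract_solution,n-caproate,20.703857560536036,gCOD
30,extract_solution,n-caprylate,5.909143521391617,gCOD
32,broth,acetate,9.370767445382043,gCOD_L
32,broth,n-butyrate,4.7991881282520925,gCOD_L
32,broth,n-caproate,1.3478320655747524,gCOD_L
32,broth,n-caprylate,0.3889553266564222,gCOD_L
32,extract_solution,n-caproate,25.103666919470783,gCOD
32,extract_solution,n-caprylate,6.802586808800243,gCOD
34,broth,acetate,9.3942285532999,gCOD_L
34,broth,n-butyrate,4.296393207247735,gCOD_L
34,broth,n-caproate,1.29757627640439,gCOD_L
34,broth,n-caprylate,0.38843530942334825,gCOD_L
34,extract_solution,n-caproate,24.470338849394746,gCOD
34,extract_solution,n-caprylate,7.55661561743966,gCOD
36,broth,acetate,8.953252344825435,gCOD_L
36,broth,n-butyrate,4.74989773613286,gCOD_L
36,broth,n-caproate,1.2234295412539964,gCOD_L
36,broth,n-caprylate,0.3364500390034096,gCOD_L
36,extract_solution,n-caproate,27.605339201752265,gCOD
36,extract_solution,n-caprylate,8.661325988632518,gCOD
39,broth,acetate,9.32361712876965,gCOD_L
39,broth,n-butyrate,4.308506364439414,gCOD_L
39,broth,n-caproate,0.7601805482359512,gCOD_L
39,broth,n-caprylate,0.3497530002181443,gCOD_L
39,extract_solution,n-caproate,38.66325489566082,gCOD
39,extract_solution,n-caprylate,12.358338418348577,gCOD
41,broth,acetate,9.14955348616629,gCOD_L
41,broth,n-butyrate,4.85714664118544,gCOD_L
41,broth,n-caproate,0.7315356382311043,gCOD_L
41,broth,n-caprylate,0.32872098992228205,gCOD_L
41,extract_solution,n-caproate,47.55655419143137,gCOD
41,extract_solution,n-caprylate,16.797259911519465,gCOD
43,broth,acetate,7.794589331574236,gCOD_L
43,broth,n-butyrate,4.52286477600454,gCOD_L
43,broth,n-caproate,0.753212277316899,gCOD_L
43,broth,n-caprylate,0.3766736049371482,gCOD_L
43,extract_solution,n-caproate,53.73285280818972,gCOD
43,extract_solution,n-caprylate,22.372924043826124,gCOD
45,broth,acetate,9.449637904094562,gCOD_L
45,broth,n-butyrate,4.345827024418624,gCOD_L
45,broth,n-caproate,0.7554510532888633,gCOD_L
45,broth,n-caprylate,0.36783692679397795,gCOD_L
45,extract_solution,n-caproate,65.9270727668651,gCOD
45,extract_solution,n-caprylate,26.382131139851435,gCOD
47,broth,acetate,9.111184716366655,gCOD_L
47,broth,n-butyrate,4.400761058366661,gCOD_L
47,broth,n-caproate,0.7000964847036648,gCOD_L
47,broth,n-caprylate,0.3487539037352848,gCOD_L
47,extract_solution,n-caproate,80.84064526870357,gCOD
47,extract_solution,n-caprylate,32.71574216831641,gCOD
49,broth,acetate,9.33191340042424,gCOD_L
49,broth,n-butyrate,4.489556197109181,gCOD_L
49,broth,n-caproate,0.7254905517649367,gCOD_L
49,broth,n-caprylate,0.3339155839554209,gCOD_L
49,extract_solution,n-caproate,83.32648042980054,gCOD
49,extract_solution,n-caprylate,35.97548448855319,gCOD
51,broth,acetate,8.491860278573721,gCOD_L
51,broth,n-butyrate,4.461992010526316,gCOD_L
51,broth,n-caproate,0.7197331211239764,gCOD_L
51,broth,n-caprylate,0.3752246576573287,gCOD_L
51,extract_solution,n-caproate,93.46453252350814,gCOD
51,extract_solution,n-caprylate,42.806952509001945,gCOD
53,broth,acetate,9.025741436497249,gCOD_L
53,broth,n-butyrate,4.669613369923995,gCOD_L
53,broth,n-caproate,0.6644407215261455,gCOD_L
53,broth,n-caprylate,0.34381941055689524,gCOD_L
53,extract_solution,n-caproate,102.07527711973344,gCOD
53,extract_solution,n-caprylate,45.07491649185737,gCOD
55,broth,acetate,8.828605926826912,gCOD_L
55,broth,n-butyrate,4.460105906300542,gCOD_L
55,broth,n-caproate,0.7592819068791641,gCOD_L
55,broth,n-caprylate,0.3663380882582987,gCOD_L
55,extract_solution,n-caproate,113.61225050417593,gCOD
55,extract_solution,n-caprylate,52.63830630046877,gCOD
57,broth,acetate,9.03472396951125,gCOD_L
57,broth,n-butyrate,4.273624700417811,gCOD_L
57,broth,n-caproate,0.7235589495488629,gCOD_L
57,broth,n-caprylate,0.3625045993558866,gCOD_L
57,extract_solution,n-caproate,127.77431598286002,gCOD
57,extract_solution,n-caprylate,54.274302693419244,gCOD
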