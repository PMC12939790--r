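environment,genotype,block,role,yield
E1,G1,B1,line,6.58929447266471
E1,G2,B2,line,4.4855605418146
E1,G3,B3,line,7.16250713779337
E1,G4,B4,line,4.20771920292828
E1,G5,B1,line,7.66180749645844
E1,G6,B2,line,7.40612528729396
E1,G7,B3,line,8.1393823394199
E1,G8,B4,line,7.38030454217891
E1,G9,B1,line,5.5211611129306
E1,G10,B2,line,4.83690500295556
E1,G11,B3,line,5.03981980415679
E1,G12,B4,line,5.92720779542071
E1,G13,B1,line,9.48974471568712
E1,G14,B2,line,6.94888416327453
E1,G15,B3,line,6.99644000880788
E1,G16,B4,line,5.51467370072585
E1,G17,B1,line,5.11496590897714
E1,G18,B2,line,5.22437883345418
E1,G19,B3,line,6.12906313834215
E1,G20,B4,line,6.67295120117475
E1,G21,B1,line,4.17773782713267
E1,G22,B2,line,5.72077081339118
E1,G23,B3,line,7.62094483250964
E1,G24,B4,line,7.21153917687886
E1,G25,B1,line,5.92610389991231
E1,G26,B2,line,7.06139132001426
E1,G27,B3,line,6.01843411850784
E1,G28,B4,line,8.62292639372153
E1,G29,B1,line,6.66688254470333
E1,G30,B2,line,6.99713598734925
E1,CHK1,B1,check,6.06499463893922
E1,CHK1,B2,check,5.98952221851232
E1,CHK1,B3,check,6.94624097556526
E1,CHK1,B4,check,7.02775062216087
E1,CHK2,B1,check,7.22232220504587
E1,CHK2,B2,check,7.02134081001443
E1,CHK2,B3,check,8.18991246982712
E1,CHK2,B4,check,6.26190969864561
E1,CHK3,B1,check,5.11954286885337
E1,CHK3,B2,check,5.68598558153843
E1,CHK3,B3,check,4.5516731047334
E1,CHK3,B4,check,7.16887486549493
E1,CHK4,B1,check,4.82966867053799
E1,CHK4,B2,check,3.42185651198701
E1,CHK4,B3,check,3.19694191111165
E1,CHK4,B4,check,2.64288914313913
E2,G1,B1,line,7.04919796953549
E2,G2,B2,line,5.28248269093672
E2,G3,B3,line,6.57582512823382
E2,G4,B4,line,6.86520592170409
E2,G5,B1,line,6.88646967701313
E2,G6,B2,line,6.59030451629214
E2,G7,B3,line,7.10161224667776
E2,G8,B4,line,8.40974594960847
E2,G9,B1,line,5.38484583620195
E2,G10,B2,line,5.54892342681056
E2,G11,B3,line,5.37913012211759
E2,G12,B4,line,7.90362681902315
E2,G13,B1,line,7.78173307330237
E2,G14,B2,line,5.27674888132994
E2,G15,B3,line,4.44509883825729
E2,G16,B4,line,6.8898736382484
E2,G17,B1,line,4.92986931253403
E2,G18,B2,line,6.43853510088636
E2,G19,B3,line,5.91063422204483
E2,G20,B4,line,7.78184986064376
E2,G21,B1,line,3.70280501037434
E2,G22,B2,line,6.45745158032355
E2,G23,B3,line,7.23486242663516
E2,G24,B4,line,8.20876134683414
E2,G25,B1,line,5.68518616285169
E2,G26,B2,line,8.13331511968505
E2,G27,B3,line,8.00909205489199
E2,G28,B4,line,7.53349404643777
E2,G29,B1,line,8.9466534057931
E2,G30,B2,line,7.54708926755567
E2,CHK1,B1,check,6.70427442432193
E2,CHK1,B2,check,6.75839442651952
E2,CHK1,B3,check,7.07921360235646
E2,CHK1,B4,check,6.47925827964539
E2,CHK2,B1,check,6.8035496065582
E2,CHK2,B2,check,7.18096936093746
E2,CHK2,B3,check,8.93568611686645
E2,CHK2,B4,check,7.58390851585974
E2,CHK3,B1,check,6.22852005117881
E2,CHK3,B2,check,8.31994005363734
E2,CHK3,B3,check,6.50425635642931
E2,CHK3,B4,check,6.72509134397804
E2,CHK4,B1,check,3.80139191963958
E2,CHK4,B2,check,3.781094290913
E2,CHK4,B3,check,3.57178476133923
E2,CHK4,B4,check,5.11744366709552
E3,G1,B1,line,8.29786932046228
E3,G2,B2,line,5.43708725711449
E3,G3,B3,line,8.81561257419035
E3,G4,B4,line,4.97665057251601
E3,G5,B1,line,8.08373628644866
E3,G6,B2,line,7.75602130049605
E3,G7,B3,line,7.28388052767512
E3,G8,B4,line,6.47566903408131
E3,G9,B1,line,7.49330875000614
E3,G10,B2,line,4.95742966755514
E3,G11,B3,line,5.57709832683445
E3,G12,B4,line,5.36030084783711
E3,G13,B1,line,8.15610441098115
E3,G14,B2,line,5.8723409709416
E3,G15,B3,line,9.65756170634504
E3,G16,B4,line,5.52048334149955
E3,G17,B1,line,6.138315091734
E3,G18,B2,line,7.33361382119566
E3,G19,B3,line,6.47407532372465
E3,G20,B4,line,8.25140485271245
E3,G21,B1,line,4.55128857336162
E3,G22,B2,line,6.24281144030474
E3,G23,B3,line,8.27803217076305
E3,G24,B4,line,7.0589839553383
E3,G25,B1,line,5.70982188576169
E3,G26,B2,line,7.927405847085
E3,G27,B3,line,6.70946738341842
E3,G28,B4,line,4.15711557370756
E3,G29,B1,line,6.4970871550283
E3,G30,B2,line,6.92686611979659
E3,CHK1,B1,check,7.47474146304235
E3,CHK1,B2,check,6.02828054264955
E3,CHK1,B3,check,4.80183009223027
E3,CHK1,B4,check,7.10478990660089
E3,CHK2,B1,check,7.28505505971974
E3,CHK2,B2,check,8.51757112936246
E3,CHK2,B3,check,6.87864465804422
E3,CHK2,B4,check,8.43860571965639
E3,CHK3,B1,check,7.24940156802669
E3,CHK3,B2,check,4.97332388093911
E3,CHK3,B3,check,7.69021492572032
E3,CHK3,B4,check,6.2117784979467
E3,CHK4,B1,check,3.35840415324184
E3,CHK4,B2,check,2.61296313512709
E3,CHK4,B3,check,3.95497371149538
E3,CHK4,B4,check,4.80290295903801
E4,G1,B1,line,10.032737292803
E4,G2,B2,line,6.45932632650909
E4,G3,B3,line,9.5214015992667
E4,G4,B4,line,6.5472255109966
E4,G5,B1,line,8.80659503310376
E4,G6,B2,line,9.5212649746027
E4,G7,B3,line,9.90144164006341
E4,G8,B4,line,8.70062953722296
E4,G9,B1,line,6.91197727485088
E4,G10,B2,line,7.40769029144067
E4,G11,B3,line,6.48425355694622
E4,G12,B4,line,10.8210351953811
E4,G13,B1,line,10.9413518303229
E4,G14,B2,line,7.71321714259725
E4,G15,B3,line,5.90388310993573
E4,G16,B4,line,7.426581427716
E4,G17,B1,line,6.60042230410382
E4,G18,B2,line,8.97332097667086
E4,G19,B3,line,6.80212801640224
E4,G20,B4,line,7.49999238319432
E4,G21,B1,line,6.32310682840584
E4,G22,B2,line,9.77598567091595
E4,G23,B3,line,9.72735057005578
E4,G24,B4,line,11.689216249461
E4,G25,B1,line,6.79799505524871
E4,G26,B2,line,8.94612391181824
E4,G27,B3,line,9.17247479768147
E4,G28,B4,line,9.01384989512559
E4,G29,B1,line,10.0719797564627
E4,G30,B2,line,6.75859320949123
E4,CHK1,B1,check,7.489794531166
E4,CHK1,B2,check,7.47702423717195
E4,CHK1,B3,check,8.49589924034954
E4,CHK1,B4,check,7.09250654509699
E4,CHK2,B1,check,10.146452938068
E4,CHK2,B2,check,9.70564321461121
E4,CHK2,B3,check,9.76460639600922
E4,CHK2,B4,check,9.3092551860942
E4,CHK3,B1,check,7.40483454736384
E4,CHK3,B2,check,9.88954007607285
E4,CHK3,B3,check,9.06258208867912
E4,CHK3,B4,check,9.52160143315392
E4,CHK4,B1,check,6.28685399952099
E4,CHK4,B2,check,5.38451974878317
E4,CHK4,B3,check,5.81701907072547
E4,CHK4,B4,check,5.51884747318871
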