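patient_id,time,y1
sim1,1,8.2783075900981693
sim1,2,9.5467808234041005
sim1,3,8.9295441394283319
sim1,4,8.1867676647830887
sim1,5,7.7101044195642112
sim1,7,6.5765240742646274
sim1,8,5.879567839782359
sim1,9,5.9611735217674759
sim1,10,6.4198737714137932
sim1,11,5.2524767137911477
sim1,13,4.9973970151268023
sim1,15,3.7010027107821779
sim1,16,4.1893540173339332
sim1,17,3.3577314386873067
sim1,18,3.1397061339595389
sim2,0,11.851299186077366
sim2,1,12.312791642004751
sim2,2,12.633100924963836
sim2,5,10.70658390561556
sim2,6,12.283967228407109
sim2,7,10.745344415532005
sim2,8,10.972435584906782
sim2,9,10.493431108834287
sim2,10,9.3996842035744255
sim2,11,10.022481211294572
sim2,12,8.8329802398480872
sim2,14,8.5673408645584388
sim2,15,8.38167230298777
sim2,16,8.1780731760226875
sim2,18,7.1082751410793339
sim2,19,7.5793043485170806
sim2,20,6.363726824824214
sim2,21,6.3343403322792344
sim2,22,6.5152594337193142
sim3,1,8.2133585994869662
sim3,2,8.1655447823296399
sim3,4,7.5107865716264737
sim3,7,6.2333287548829928
sim3,8,5.8883989948470621
sim3,9,5.7111645862011038
sim3,10,7.0209088125712871
sim3,12,6.7095837190900687
sim3,13,5.7537187103138461
sim3,14,5.1844030432849051
sim3,15,3.9962011866885829
sim3,16,3.0595304467094557
sim3,17,2.7146020036276481
sim3,18,2.4412943318756835
sim4,0,9.4302924212024717
sim4,1,7.1717015601540535
sim4,3,7.5702084402333831
sim4,4,7.5485672866953193
sim4,5,7.2799318798174957
sim4,6,7.5998352069537702
sim4,7,6.7331194112851191
sim4,8,7.444313460296744
sim4,9,7.8039246168271594
sim4,10,7.139495553085907
sim4,11,6.6262230200706149
sim4,12,6.8547050068921322
sim4,13,5.5442265888071161
sim4,14,6.7056327157009115
sim4,15,6.2911953352110617
sim4,16,5.1585317230859733
sim4,17,5.8860773755971563
sim4,18,5.1129604133428908
sim4,19,5.3984792812707205
sim5,0,10.755474781385935
sim5,1,10.635196071188107
sim5,2,10.132439784056327
sim5,3,11.485776811800813
sim5,4,10.249196477599895
sim5,6,10.416204449134753
sim5,7,9.7058336455168224
sim5,8,9.6361082445464685
sim5,9,8.5796369384400766
sim5,10,8.9680067568736632
sim5,11,9.5748651933776685
sim5,12,8.1975956511011141
sim5,13,8.4070774630627678
sim5,14,8.2216006972346367
sim5,16,8.6855668550313414
sim5,17,8.3655498025953854
sim5,19,5.8303258246004059
sim5,20,6.8529422793307937
sim5,22,5.9843759058069264
sim5,24,4.9217427828370122
sim5,25,5.1646176230352747
sim5,26,4.8718860218439337
sim5,27,4.6145135757767175
sim5,28,3.4221195490989222
sim6,0,9.1677815454536642
sim6,1,8.3229553983500839
sim6,2,7.4884343082712421
sim6,3,7.7981996281492609
sim6,6,5.5803591689844056
sim6,7,5.712375989417052
sim6,8,4.6442404298643369
sim6,9,5.590611283020765
sim6,10,4.3995533839351708
sim6,11,4.4420202541018785
sim6,12,4.9836934068493504
sim6,13,3.7888427528875441
sim6,14,4.2161665173607465
sim6,16,3.5797917359542146
sim7,0,10.684369873603805
sim7,1,8.9343762851996331
sim7,3,7.984126107185709
sim7,4,8.0214335888167696
sim7,5,6.6815775761992819
sim7,6,7.4220620521969014
sim7,7,6.8772751246760153
sim7,8,6.7603772025442481
sim7,9,7.0933478710361495
sim7,10,5.9058261891541637
sim7,12,5.3680981871565132
sim7,13,4.5698713597676992
sim7,14,3.9479620523512917
sim7,16,3.6042748143251666
sim7,19,3.1953009062572395
sim7,20,3.1372807265684681
sim7,21,2.2390621967805542
sim7,22,2.1808025201539345
sim7,23,2.5211226492822094
sim8,0,9.9895309801439467
sim8,1,9.8843806398959551
sim8,2,9.79586153882269
sim8,3,10.449433651076689
sim8,4,9.0145092297553955
sim8,5,8.8486936663560858
sim8,6,9.4888930719218578
sim8,7,8.5673555069053986
sim8,8,8.4941972121492757
sim8,9,7.3829039329399642
sim8,11,7.5306624507808877
sim8,12,7.3808571034777746
sim8,13,7.6310509287902972
sim8,14,6.531601013657661
sim8,15,6.4630551186853671
sim8,16,5.9102805764109885
sim8,18,6.0722962689559585
sim8,20,5.2325697116092194
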