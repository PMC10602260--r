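"shoot_id","date_day","internode_index","length_m"
"shoot1",0,1,0.0159611016901346
"shoot1",0,2,0.0163101871719552
"shoot1",0,3,0.0167743312367261
"shoot1",0,4,0.0158867494727698
"shoot1",0,5,0.0162239390990464
"shoot1",0,6,0.0162930936319454
"shoot1",0,7,0.0164817219018896
"shoot1",0,8,0.0161722845733247
"shoot1",0,9,0.0442207242956649
"shoot1",0,10,0.042382194613912
"shoot1",0,11,0.0428564899483449
"shoot1",0,12,0.0433427363733779
"shoot1",3,1,0.0161228738812935
"shoot1",3,2,0.0163101871719552
"shoot1",3,3,0.0168396712723932
"shoot1",3,4,0.0158867494727698
"shoot1",3,5,0.0165380700732123
"shoot1",3,6,0.0162930936319454
"shoot1",3,7,0.0165825258720485
"shoot1",3,8,0.0163910952018158
"shoot1",3,9,0.0602682336501035
"shoot1",3,10,0.0564293977430015
"shoot1",3,11,0.0596671453451055
"shoot1",3,12,0.0601043253712363
"shoot1",6,1,0.0162516048567121
"shoot1",6,2,0.0163101871719552
"shoot1",6,3,0.0168396712723932
"shoot1",6,4,0.0160572706243183
"shoot1",6,5,0.0165380700732123
"shoot1",6,6,0.0163444050986434
"shoot1",6,7,0.0165825258720485
"shoot1",6,8,0.0163910952018158
"shoot1",6,9,0.0746904062745962
"shoot1",6,10,0.072685739680317
"shoot1",6,11,0.0719732744040751
"shoot1",6,12,0.0722343111559174
"shoot2",0,1,0.0159403597235577
"shoot2",0,2,0.0161552067052213
"shoot2",0,3,0.0163343242031361
"shoot2",0,4,0.0158798382668103
"shoot2",0,5,0.0163137541567746
"shoot2",0,6,0.016259793231807
"shoot2",0,7,0.0162777844888968
"shoot2",0,8,0.0166169808125436
"shoot2",0,9,0.04147649692373
"shoot2",0,10,0.0435910324030979
"shoot2",0,11,0.0418716272663217
"shoot2",0,12,0.0415492597190616
"shoot2",3,1,0.0160188433550616
"shoot2",3,2,0.0163323198279732
"shoot2",3,3,0.0163343242031361
"shoot2",3,4,0.0161503186509368
"shoot2",3,5,0.0163137541567746
"shoot2",3,6,0.016259793231807
"shoot2",3,7,0.0166528135021859
"shoot2",3,8,0.0166169808125436
"shoot2",3,9,0.0571351264194665
"shoot2",3,10,0.0567209006518306
"shoot2",3,11,0.0575649693730947
"shoot2",3,12,0.0559053050899813
"shoot2",6,1,0.0160933123964273
"shoot2",6,2,0.0163323198279732
"shoot2",6,3,0.0166316120432472
"shoot2",6,4,0.0165822732998185
"shoot2",6,5,0.0163137541567746
"shoot2",6,6,0.016259793231807
"shoot2",6,7,0.0166528135021859
"shoot2",6,8,0.0166169808125436
"shoot2",6,9,0.0741716995872222
"shoot2",6,10,0.0741847356249198
"shoot2",6,11,0.0725869950626838
"shoot2",6,12,0.0741387751656314
"shoot3",0,1,0.0163205982449967
"shoot3",0,2,0.016074642933315
"shoot3",0,3,0.0165422183625817
"shoot3",0,4,0.0164448526646175
"shoot3",0,5,0.0167903659875155
"shoot3",0,6,0.0164755657155038
"shoot3",0,7,0.0158388847414964
"shoot3",0,8,0.0161808754710583
"shoot3",0,9,0.0441430224813914
"shoot3",0,10,0.0440374910399845
"shoot3",0,11,0.0429843530061507
"shoot3",0,12,0.0425133636364845
"shoot3",3,1,0.0163749717371801
"shoot3",3,2,0.0162353370567536
"shoot3",3,3,0.0165422183625817
"shoot3",3,4,0.0164448526646175
"shoot3",3,5,0.0167903659875155
"shoot3",3,6,0.0164755657155038
"shoot3",3,7,0.0162174129741924
"shoot3",3,8,0.0161808754710583
"shoot3",3,9,0.0596089109390586
"shoot3",3,10,0.0579912511004363
"shoot3",3,11,0.059331551061496
"shoot3",3,12,0.0593085758289704
"shoot3",6,1,0.0164438384969199
"shoot3",6,2,0.0162353370567536
"shoot3",6,3,0.0166633315425312
"shoot3",6,4,0.0165484044910362
"shoot3",6,5,0.0167903659875155
"shoot3",6,6,0.0166580990158238
"shoot3",6,7,0.0162999524783015
"shoot3",6,8,0.0165954997689971
"shoot3",6,9,0.0720056179099612
"shoot3",6,10,0.070964842927058
"shoot3",6,11,0.0743698787391057
"shoot3",6,12,0.0725109779313513
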