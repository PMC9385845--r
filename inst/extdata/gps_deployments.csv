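transmitter_id,type,deploy_date,country,region,lat,lon,age,sex,weight_g,end_date,migration
180777,OT-15-2GC,2018-06-13,DE,Hesse,50.576,8.690,Ad,f,460,2020-02-12,Yes (FR)
180786,OT-15-2GC,2018-06-29,DE,Hesse,50.568,8.672,Ad,f,555,2021-05-31,No
180781,OT-15-2GC,2018-12-13,DE,Hesse,50.566,8.675,Ad,f,580,2020-01-17,No
182891,OT-15-2G,2019-02-27,DE,Hesse,50.569,8.673,Ad,f,550,2021-04-15,No
182890,OT-15-2G,2019-03-19,DE,Hesse,50.587,8.677,Ad,f,535,2021-05-31,No
180784,OT-15-2GC,2019-05-03,DE,Hesse,50.571,8.674,Ad,f,635,2021-05-31,Yes (FR)
191391,OT-15-2G,2019-06-14,DE,Hesse,50.571,8.671,Ad,f,475,2021-05-31,Yes (DE)
190758,OT-15-3G,2019-06-18,DE,Hesse,50.839,8.677,Ad,f,510,2020-10-31,Yes (FR)
191390,OT-15-2G,2019-07-10,DE,Hesse,50.576,8.690,Ad,m,530,2021-05-31,No
191392,OT-15-2G,2019-07-22,DE,Hesse,50.569,8.673,Ad,m,560,2021-05-31,No
191389_A,OT-15-2G,2019-07-29,DE,Hesse,50.568,8.672,Ad,f,540,2020-02-29,No
190213,OT-15-2G,2019-07-30,DE,Hesse,50.576,8.690,Ad,f,540,2021-05-31,Yes (FR)
180778,OT-15-2G,2019-07-31,PO,Lisbon,38.722,-9.193,Ad,m,390,2021-05-31,No
180779_A,OT-15-2G,2019-07-31,PO,Lisbon,38.722,-9.193,Ad,f,428,2020-04-14,No
180780_A,OT-15-2G,2019-08-01,PO,Lisbon,38.722,-9.193,Juv,m,398,2019-11-16,No
180782_A,OT-15-2G,2019-08-14,PO,Lisbon,38.722,-9.193,Ad,f,385,2020-09-20,No
180783,OT-15-2G,2019-08-14,PO,Lisbon,38.722,-9.193,Ad,f,395,2021-05-31,No
180785_A,OT-15-2G,2019-08-14,PO,Lisbon,38.722,-9.193,Juv,m,385,2019-11-23,No
190759,OT-15-3G,2020-04-24,DE,Hesse,50.572,8.672,Ad,f,480,2021-04-08,No
190760,OT-15-3G,2020-06-10,DE,Hesse,50.571,8.671,Ad,f,515,2020-12-04,No
190761,OT-15-3G,2020-06-12,DE,Hesse,50.571,8.671,Ad,m,540,2021-05-31,No
190762,OT-15-3G,2020-06-12,DE,Hesse,50.571,8.671,Ad,f,520,2021-04-04,No
190763,OT-15-3G,2020-06-12,DE,Hesse,50.571,8.671,Ad,f,545,2021-03-09,Yes (DE)
190764,OT-15-3G,2020-06-16,DE,Hesse,50.571,8.671,Juv,m,430,2021-05-31,Yes (DE)
190765,OT-15-3G,2020-06-18,DE,Hesse,50.571,8.671,Ad,f,500,2020-09-27,No
190766,OT-15-3G,2020-06-18,DE,Hesse,50.571,8.671,Ad,m,450,2021-02-16,No
180779_B,OT-15-2G,2020-06-25,PO,Lisbon,38.722,-9.193,Ad,f,498,2021-05-31,No
180780_B,OT-15-2G,2020-06-30,PO,Lisbon,38.722,-9.193,Ad,m,498,2021-05-31,No
180785_B,OT-15-2G,2020-08-25,PO,Lisbon,38.722,-9.193,Ad,m,464,2021-05-31,No
191389_B,OT-15-2G,2020-08-31,PO,Lisbon,38.722,-9.193,Juv,f,380,2021-05-31,No
180782_B,OT-15-2G,2021-03-31,DE,Hesse,50.569,8.673,Ad,f,525,2021-05-31,-
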