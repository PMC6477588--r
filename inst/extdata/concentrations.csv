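animal,arm,matrix,time_hr,concentration,unit
IV01,IVnP,plasma,0.5,153,ng/mL
IV01,IVnP,lung,0.5,5850,ng/g
IV02,IVnP,plasma,0.5,205,ng/mL
IV02,IVnP,lung,0.5,5250,ng/g
IV03,IVnP,plasma,0.5,261,ng/mL
IV03,IVnP,lung,0.5,6300,ng/g
IV04,IVnP,plasma,6,70.5,ng/mL
IV04,IVnP,lung,6,2665,ng/g
IV05,IVnP,plasma,6,66.7,ng/mL
IV05,IVnP,lung,6,2880,ng/g
IV06,IVnP,plasma,6,49.3,ng/mL
IV06,IVnP,lung,6,2645,ng/g
IV07,IVnP,plasma,12,18.9,ng/mL
IV07,IVnP,lung,12,1045,ng/g
IV08,IVnP,plasma,12,20,ng/mL
IV08,IVnP,lung,12,1145,ng/g
IV09,IVnP,plasma,12,21.1,ng/mL
IV09,IVnP,lung,12,1320,ng/g
IV10,IVnP,plasma,24,9.46,ng/mL
IV10,IVnP,lung,24,386,ng/g
IV11,IVnP,plasma,24,16.3,ng/mL
IV11,IVnP,lung,24,825,ng/g
IV12,IVnP,plasma,24,20.1,ng/mL
IV12,IVnP,lung,24,730,ng/g
IV13,IVnP,plasma,48,5.08,ng/mL
IV13,IVnP,lung,48,307,ng/g
IV14,IVnP,plasma,48,1.56,ng/mL
IV14,IVnP,lung,48,190,ng/g
IV15,IVnP,plasma,48,2.3,ng/mL
IV15,IVnP,lung,48,237,ng/g
IV16,IVnP,plasma,72,BQL,ng/mL
IV16,IVnP,lung,72,101,ng/g
IV17,IVnP,plasma,72,1.05,ng/mL
IV17,IVnP,lung,72,221,ng/g
IV18,IVnP,plasma,72,BQL,ng/mL
IV18,IVnP,lung,72,113,ng/g
IV19,IVnP,plasma,120,BQL,ng/mL
IV19,IVnP,lung,120,BQL,ng/g
IV20,IVnP,plasma,120,BQL,ng/mL
IV20,IVnP,lung,120,BQL,ng/g
IV21,IVnP,plasma,120,BQL,ng/mL
IV21,IVnP,lung,120,BQL,ng/g
IV22,IVnP,plasma,168,BQL,ng/mL
IV22,IVnP,lung,168,BQL,ng/g
IV23,IVnP,plasma,168,BQL,ng/mL
IV23,IVnP,lung,168,BQL,ng/g
IV24,IVnP,plasma,168,BQL,ng/mL
IV24,IVnP,lung,168,BQL,ng/g
IV25,IVnP,plasma,240,BQL,ng/mL
IV25,IVnP,lung,240,BQL,ng/g
IV26,IVnP,plasma,240,BQL,ng/mL
IV26,IVnP,lung,240,BQL,ng/g
IV27,IVnP,plasma,240,BQL,ng/mL
IV27,IVnP,lung,240,BQL,ng/g
IV28,IVnP,plasma,336,BQL,ng/mL
IV28,IVnP,lung,336,BQL,ng/g
IV29,IVnP,plasma,336,BQL,ng/mL
IV29,IVnP,lung,336,BQL,ng/g
IV30,IVnP,plasma,336,BQL,ng/mL
IV30,IVnP,lung,336,BQL,ng/g
LD01,IHNP-LD,plasma,0.5,15.6,ng/mL
LD01,IHNP-LD,lung,0.5,19450,ng/g
LD02,IHNP-LD,plasma,0.5,12.1,ng/mL
LD02,IHNP-LD,lung,0.5,17700,ng/g
LD03,IHNP-LD,plasma,0.5,7.09,ng/mL
LD03,IHNP-LD,lung,0.5,25850,ng/g
LD04,IHNP-LD,plasma,6,3.44,ng/mL
LD04,IHNP-LD,lung,6,6700,ng/g
LD05,IHNP-LD,plasma,6,2.37,ng/mL
LD05,IHNP-LD,lung,6,3945,ng/g
LD06,IHNP-LD,plasma,6,2.81,ng/mL
LD06,IHNP-LD,lung,6,4325,ng/g
LD07,IHNP-LD,plasma,12,5.29,ng/mL
LD07,IHNP-LD,lung,12,6200,ng/g
LD08,IHNP-LD,plasma,12,2.08,ng/mL
LD08,IHNP-LD,lung,12,5550,ng/g
LD09,IHNP-LD,plasma,12,2.67,ng/mL
LD09,IHNP-LD,lung,12,4355,ng/g
LD10,IHNP-LD,plasma,24,BQL,ng/mL
LD10,IHNP-LD,lung,24,2325,ng/g
LD11,IHNP-LD,plasma,24,1.16,ng/mL
LD11,IHNP-LD,lung,24,2045,ng/g
LD12,IHNP-LD,plasma,24,1.36,ng/mL
LD12,IHNP-LD,lung,24,4655,ng/g
LD13,IHNP-LD,plasma,48,BQL,ng/mL
LD13,IHNP-LD,lung,48,850,ng/g
LD14,IHNP-LD,plasma,48,BQL,ng/mL
LD14,IHNP-LD,lung,48,1530,ng/g
LD15,IHNP-LD,plasma,48,BQL,ng/mL
LD15,IHNP-LD,lung,48,1360,ng/g
LD16,IHNP-LD,plasma,72,BQL,ng/mL
LD16,IHNP-LD,lung,72,950,ng/g
LD17,IHNP-LD,plasma,72,BQL,ng/mL
LD17,IHNP-LD,lung,72,1385,ng/g
LD18,IHNP-LD,plasma,72,BQL,ng/mL
LD18,IHNP-LD,lung,72,515,ng/g
LD19,IHNP-LD,plasma,120,BQL,ng/mL
LD19,IHNP-LD,lung,120,1500,ng/g
LD20,IHNP-LD,plasma,120,BQL,ng/mL
LD20,IHNP-LD,lung,120,890,ng/g
LD21,IHNP-LD,plasma,120,BQL,ng/mL
LD21,IHNP-LD,lung,120,745,ng/g
LD22,IHNP-LD,plasma,168,BQL,ng/mL
LD22,IHNP-LD,lung,168,309,ng/g
LD23,IHNP-LD,plasma,168,BQL,ng/mL
LD23,IHNP-LD,lung,168,695,ng/g
LD24,IHNP-LD,plasma,168,BQL,ng/mL
LD24,IHNP-LD,lung,168,129,ng/g
LD25,IHNP-LD,plasma,240,BQL,ng/mL
LD25,IHNP-LD,lung,240,58,ng/g
LD26,IHNP-LD,plasma,240,BQL,ng/mL
LD26,IHNP-LD,lung,240,151,ng/g
LD27,IHNP-LD,plasma,240,BQL,ng/mL
LD27,IHNP-LD,lung,240,117,ng/g
LD28,IHNP-LD,plasma,336,BQL,ng/mL
LD28,IHNP-LD,lung,336,BQL,ng/g
LD29,IHNP-LD,plasma,336,BQL,ng/mL
LD29,IHNP-LD,lung,336,55.5,ng/g
LD30,IHNP-LD,plasma,336,BQL,ng/mL
LD30,IHNP-LD,lung,336,BQL,ng/g
HD01,IHNP-HD,plasma,0.5,10.8,ng/mL
HD01,IHNP-HD,lung,0.5,40400,ng/g
HD02,IHNP-HD,plasma,0.5,21.3,ng/mL
HD02,IHNP-HD,lung,0.5,43800,ng/g
HD03,IHNP-HD,plasma,0.5,15.6,ng/mL
HD03,IHNP-HD,lung,0.5,40600,ng/g
HD04,IHNP-HD,plasma,6,6.56,ng/mL
HD04,IHNP-HD,lung,6,15500,ng/g
HD05,IHNP-HD,plasma,6,4.35,ng/mL
HD05,IHNP-HD,lung,6,20400,ng/g
HD06,IHNP-HD,plasma,6,6.15,ng/mL
HD06,IHNP-HD,lung,6,26500,ng/g
HD07,IHNP-HD,plasma,12,7.14,ng/mL
HD07,IHNP-HD,lung,12,17050,ng/g
HD08,IHNP-HD,plasma,12,3.47,ng/mL
HD08,IHNP-HD,lung,12,13500,ng/g
HD09,IHNP-HD,plasma,12,4.23,ng/mL
HD09,IHNP-HD,lung,12,13550,ng/g
HD10,IHNP-HD,plasma,24,1.47,ng/mL
HD10,IHNP-HD,lung,24,10300,ng/g
HD11,IHNP-HD,plasma,24,3.11,ng/mL
HD11,IHNP-HD,lung,24,11700,ng/g
HD12,IHNP-HD,plasma,24,1.31,ng/mL
HD12,IHNP-HD,lung,24,12300,ng/g
HD13,IHNP-HD,plasma,48,1.21,ng/mL
HD13,IHNP-HD,lung,48,6000,ng/g
HD14,IHNP-HD,plasma,48,BQL,ng/mL
HD14,IHNP-HD,lung,48,7300,ng/g
HD15,IHNP-HD,plasma,48,BQL,ng/mL
HD15,IHNP-HD,lung,48,6800,ng/g
HD16,IHNP-HD,plasma,72,BQL,ng/mL
HD16,IHNP-HD,lung,72,4375,ng/g
HD17,IHNP-HD,plasma,72,1.06,ng/mL
HD17,IHNP-HD,lung,72,4735,ng/g
HD18,IHNP-HD,plasma,72,BQL,ng/mL
HD18,IHNP-HD,lung,72,2750,ng/g
HD19,IHNP-HD,plasma,120,BQL,ng/mL
HD19,IHNP-HD,lung,120,1570,ng/g
HD20,IHNP-HD,plasma,120,BQL,ng/mL
HD20,IHNP-HD,lung,120,1110,ng/g
HD21,IHNP-HD,plasma,120,BQL,ng/mL
HD21,IHNP-HD,lung,120,3090,ng/g
HD22,IHNP-HD,plasma,168,BQL,ng/mL
HD22,IHNP-HD,lung,168,3395,ng/g
HD23,IHNP-HD,plasma,168,BQL,ng/mL
HD23,IHNP-HD,lung,168,1410,ng/g
HD24,IHNP-HD,plasma,168,BQL,ng/mL
HD24,IHNP-HD,lung,168,1625,ng/g
HD25,IHNP-HD,plasma,240,BQL,ng/mL
HD25,IHNP-HD,lung,240,271,ng/g
HD26,IHNP-HD,plasma,240,BQL,ng/mL
HD26,IHNP-HD,lung,240,448,ng/g
HD27,IHNP-HD,plasma,240,BQL,ng/mL
HD27,IHNP-HD,lung,240,570,ng/g
HD28,IHNP-HD,plasma,336,BQL,ng/mL
HD28,IHNP-HD,lung,336,233,ng/g
HD29,IHNP-HD,plasma,336,BQL,ng/mL
HD29,IHNP-HD,lung,336,367,ng/g
HD30,IHNP-HD,plasma,336,BQL,ng/mL
HD30,IHNP-HD,lung,336,216,ng/g
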