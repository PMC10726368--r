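molecule,axis,b_eq,delta_cvb,delta_vb,delta_vib,b0,b_exp
quinoline,a,3160.8,11.7,-3.9,-22.4,3146.2,3145.4
quinoline,b,1276.3,4.8,-1.3,-7.9,1271.9,1271.6
quinoline,c,909.2,3.4,-1.0,-5.7,905.9,905.7
isoquinoline,a,3214.1,11.9,-3.6,-23.5,3198.9,3199.0
isoquinoline,b,1242.8,4.7,-1.5,-7.5,1238.5,1237.9
isoquinoline,c,896.3,3.3,-1.0,-5.6,893.0,892.8
acridine,a,2163.3,8.0,-1.3,-16.0,2154.0,2154.4
acridine,b,468.0,1.8,-0.3,-2.7,466.8,466.6
acridine,c,384.8,1.5,-0.3,-2.2,383.8,383.6
phenanthridine,a,1649.3,6.2,-1.1,-11.0,1643.4,1642.5
phenanthridine,b,559.3,2.1,-0.4,-3.5,557.5,557.7
phenanthridine,c,417.7,1.6,-0.3,-2.5,416.5,416.5
benzothiophene,a,3165.6,12.6,-2.0,-21.2,3155.4,3153.8
benzothiophene,b,1313.1,5.6,-0.9,-7.3,1310.5,1309.7
benzothiophene,c,928.1,3.9,-0.6,-5.4,926.0,925.5
benzonitrile,a,5681.4,21.9,-5.3,-40.4,5657.6,5655.3
benzonitrile,b,1548.0,6.0,-1.0,-6.0,1547.0,1546.9
benzonitrile,c,1216.6,4.6,-0.8,-5.8,1214.6,1214.4
3-cyanopyridine,a,5852.3,21.7,-3.9,-39.5,5830.6,5823.1
3-cyanopyridine,b,1572.2,6.0,-0.8,-6.1,1571.3,1571.3
3-cyanopyridine,c,1239.3,4.7,-0.7,-5.8,1237.5,1237.2
1-cyanonaphthalene,a,1483.8,5.8,-2.1,-8.2,1479.3,1478.9
1-cyanonaphthalene,b,959.4,3.5,-1.0,-5.3,956.6,956.8
1-cyanonaphthalene,c,582.7,2.1,-0.6,-3.2,581.0,581.0
2-cyanonaphthalene,a,2717.6,10.2,-2.7,-17.8,2707.3,2707.0
2-cyanonaphthalene,b,607.2,2.3,-0.4,-3.1,606.0,606.1
2-cyanonaphthalene,c,496.3,1.9,-0.4,-2.6,495.2,495.3
9-cyanophenanthrene,a,848.5,3.2,-0.6,-4.9,846.2,846.1
9-cyanophenanthrene,b,487.6,1.9,-0.4,-2.8,486.3,486.4
9-cyanophenanthrene,c,309.7,1.2,-0.2,-1.7,309.0,308.9
9-cyanoanthracene,a,987.3,3.6,-0.5,-5.1,985.3,985.8
9-cyanoanthracene,b,452.8,1.7,-0.4,-2.8,451.3,451.2
9-cyanoanthracene,c,310.4,1.2,-0.3,-1.7,309.6,309.6
2-cyanoindene,a,3773.0,13.8,-2.8,-28.3,3755.7,3754.5
2-cyanoindene,b,676.6,2.6,-0.4,-3.0,675.8,676.0
2-cyanoindene,c,575.8,2.2,-0.4,-2.7,574.9,575.0
cyanonorbornadiene,a,3854.3,14.3,-1.1,-32.0,3835.5,3831.7
cyanonorbornadiene,b,1318.3,4.9,-0.4,-6.6,1316.2,1316.2
cyanonorbornadiene,c,1243.2,4.7,-0.5,-6.0,1241.4,1241.8
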