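molecule,axis,b_eq,delta_cvb,delta_cv2,delta_vb,delta_vib,delta_el,b0,b_exp
pyridine,a,6067.4,25.3,NA,-5.1,-44.7,-0.3,6042.9,6039.3
pyridine,b,5832.9,23.0,NA,-5.1,-37.1,-0.3,5813.7,5804.9
pyridine,c,2973.6,12.4,NA,-2.6,-21.3,0.1,2962.1,2959.2
pyrimidine,a,6304.9,25.1,NA,-1.2,-43.8,-0.3,6285.0,6276.8
pyrimidine,b,6098.2,24.0,NA,-2.9,-40.2,-0.4,6079.1,6067.2
pyrimidine,c,3099.9,12.2,NA,-1.0,-21.8,0.1,3089.3,3084.4
pyridazine,a,6278.9,24.0,NA,-3.3,-48.2,-0.4,6251.4,6243.0
pyridazine,b,5988.6,23.7,NA,-2.7,-37.5,-0.5,5972.1,5961.1
pyridazine,c,3065.2,11.9,NA,-1.5,-22.2,0.1,3053.4,3048.7
pyrrole,a,9174.2,34.9,NA,-2.9,-73.7,-0.5,9132.5,9130.6
pyrrole,b,9042.5,33.8,NA,-7.0,-69.8,-0.3,8999.5,9001.3
pyrrole,c,4554.0,17.1,NA,-2.5,-36.7,0.2,4531.9,4532.1
imidazole,a,9769.3,38.2,NA,-0.2,-80.0,-0.5,9727.3,9725.3
imidazole,b,9418.1,36.8,NA,-4.4,-77.1,-0.6,9373.5,9374.0
imidazole,c,4795.2,18.8,NA,-1.2,-40.9,0.2,4771.9,4771.9
furan,a,9493.0,35.6,NA,-3.0,-78.7,-0.5,9446.9,9447.1
furan,b,9287.1,34.7,NA,-8.9,-65.4,-0.5,9247.5,9246.7
furan,c,4694.5,17.5,NA,-3.0,-38.3,0.1,4670.7,4670.8
2-furonitrile,a,9259.8,34.7,NA,-7.7,-67.6,-0.5,9219.2,9220.3
2-furonitrile,b,2028.5,8.2,NA,-0.9,-7.0,-0.4,2028.8,2029.2
2-furonitrile,c,1664.0,6.7,NA,-0.9,-7.4,0.1,1662.4,1662.0
thiophene,a,8077.0,34.1,NA,-3.2,-59.5,0.4,8048.4,8041.8
thiophene,b,5434.1,24.6,NA,-3.1,-29.6,0.2,5426.0,5418.1
thiophene,c,3248.5,14.3,NA,-1.6,-21.7,-0.1,3239.5,3235.8
uracil,a,3899.7,15.3,15.2,-1.3,-27.7,-0.1,3886.1,3883.9
uracil,b,2025.8,8.3,6.6,-0.1,-10.6,-0.1,2023.4,2023.7
uracil,c,1333.2,5.5,4.7,-0.2,-7.4,0.0,1331.0,1330.9
2-thiouracil,a,3568.3,15.4,14.8,-2.7,-22.9,-0.1,3558.1,3555.1
2-thiouracil,b,1316.3,6.4,5.8,-0.4,-6.4,0.0,1315.9,1315.0
2-thiouracil,c,961.6,4.5,4.1,-0.4,-4.9,0.0,960.8,960.0
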