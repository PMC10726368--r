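molecule,axis,b_eq,delta_cvb,delta_cv2,delta_vb,delta_vib,b0,b_exp,excluded
naphthalene,a,3133.9,11.6,13.0,-4.2,-22.7,3118.6,3119.4,FALSE
naphthalene,b,1237.8,4.7,5.0,-2.5,-7.7,1232.9,1233.0,FALSE
naphthalene,c,887.3,3.4,3.7,-1.3,-5.6,883.8,883.9,FALSE
anthracene,a,2155.3,8.0,8.5,-3.0,-16.0,2144.3,2146.2,FALSE
anthracene,b,454.2,1.7,1.7,-0.6,-2.7,452.6,452.5,FALSE
anthracene,c,375.1,1.4,1.7,-0.5,-2.2,373.8,374.0,FALSE
phenanthrene,a,1622.0,6.0,6.5,-2.3,-11.0,1614.7,1606.7,TRUE
phenanthrene,b,554.5,2.1,2.2,-0.7,-3.6,552.3,547.7,TRUE
phenanthrene,c,413.2,1.6,1.7,-0.5,-2.5,411.8,409.6,TRUE
pyrene,a,1015.3,3.9,4.2,-1.4,-6.7,1011.1,1010.1,FALSE
pyrene,b,558.6,2.1,2.2,-0.9,-3.4,556.4,556.5,FALSE
pyrene,c,360.4,1.4,1.3,-0.5,-2.2,359.1,358.9,FALSE
azulene,a,2858.0,10.6,11.3,-3.6,-20.1,2844.9,2842.0,FALSE
azulene,b,1259.8,4.7,4.9,-1.7,-7.7,1255.1,1254.8,FALSE
azulene,c,874.4,3.3,3.4,-1.2,-5.4,871.1,870.7,FALSE
acenaphthylene,a,1516.1,5.7,NA,-1.0,-9.7,1511.1,1511.8,FALSE
acenaphthylene,b,1224.8,4.6,NA,-1.0,-7.7,1220.7,1220.6,FALSE
acenaphthylene,c,677.5,2.5,NA,-0.5,-4.2,675.3,675.5,FALSE
indene,a,3792.5,13.1,NA,-2.1,-27.9,3775.6,3775.0,FALSE
indene,b,1584.7,6.0,NA,-1.2,-9.5,1580.0,1580.9,FALSE
indene,c,1125.4,4.4,NA,-1.0,-7.0,1121.8,1122.2,FALSE
norbornadiene,a,4305.7,16.6,NA,-3.0,-40.6,4278.7,4273.6,FALSE
norbornadiene,b,3628.6,15.2,NA,-1.5,-32.0,3610.3,3610.3,FALSE
norbornadiene,c,3199.4,11.5,NA,-1.0,-24.0,3185.9,3186.4,FALSE
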