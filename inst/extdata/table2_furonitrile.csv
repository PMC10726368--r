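parameter,kind,exp,cheap,rdsd,corrected
C2-N1,bond,1.1587,1.1574,1.1623,1.1595
C2-C3,bond,1.4173,1.4177,1.4179,1.4157
C3-C4,bond,1.3623,1.3627,1.3649,1.3633
C3-O5,bond,1.3590,1.3597,1.3633,1.3606
O5-C7,bond,1.3544,1.3535,1.3568,1.3541
C7-C9,bond,1.3572,1.3566,1.3607,1.3591
C4-H6,bond,1.0747,1.0747,1.0776,1.0765
C7-H8,bond,1.0737,1.0737,1.0766,1.0754
C9-H10,bond,1.0744,1.0744,1.0774,1.0762
C3C2N1,angle,179.70,178.59,178.65,178.65
C4C3C2,angle,131.06,131.59,131.75,131.75
C4C3O5,angle,110.93,110.90,110.94,110.94
C3O5C7,angle,106.24,106.22,106.36,106.36
O5C7C9,angle,111.07,110.90,110.94,110.94
C3C4H6,angle,125.93,125.93,125.91,125.91
O5C7H8,angle,115.65,115.65,115.65,115.65
C4C9H10,angle,127.47,127.47,127.43,127.43
C7C9H10,angle,126.49,126.49,126.56,126.56
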