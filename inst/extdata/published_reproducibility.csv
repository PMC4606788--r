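patient,protein,category,day1_pct,day2_pct,diff_pct,ci_low_pct,ci_high_pct,n_day1,n_day2
P1,coxi,positive,0.2,0.2,0.1,-0.4,0.6,424,1258
P1,coxi,int_plus,3.8,4.5,-0.8,-2.9,1.4,424,1258
P1,coxi,int_minus,15.3,17.3,-2.0,-6.0,2.0,424,1258
P1,coxi,deficient,80.7,78.0,2.7,-1.7,7.1,424,1258
P1,ndufb8,positive,99.8,99.6,0.2,-0.4,0.7,424,1258
P1,ndufb8,int_plus,0.2,0.3,-0.1,-0.6,0.5,424,1258
P1,ndufb8,int_minus,0.0,0.1,-0.1,-0.2,0.1,424,1258
P2,coxi,positive,99.9,100.0,-0.1,-0.3,0.1,823,932
P2,coxi,int_plus,0.1,0.0,0.1,-0.1,0.3,823,932
P2,ndufb8,positive,9.6,11.9,-2.3,-5.0,0.5,823,932
P2,ndufb8,int_plus,0.4,0.3,0.2,-0.4,0.7,823,932
P2,ndufb8,int_minus,0.2,0.1,0.1,-0.2,0.5,823,932
P2,ndufb8,deficient,89.7,87.8,2.0,-0.8,4.8,823,932
P11,coxi,positive,72.8,71.2,1.7,-1.2,4.5,1589,2400
P11,coxi,int_plus,5.3,5.2,0.1,-1.3,1.5,1589,2400
P11,coxi,int_minus,3.2,2.7,0.5,-0.6,1.6,1589,2400
P11,coxi,deficient,18.7,21.0,-2.3,-4.8,0.3,1589,2400
P11,ndufb8,positive,63.4,54.4,9.0,5.9,12.1,1589,2400
P11,ndufb8,int_plus,12.4,19.0,-6.6,-8.9,-4.4,1589,2400
P11,ndufb8,int_minus,4.7,4.1,0.6,-0.7,1.9,1589,2400
P11,ndufb8,deficient,19.6,22.5,-2.9,-5.5,0.3,1589,2400
P17,coxi,positive,91.5,91.5,0.0,-2.0,2.1,1362,1512
P17,coxi,int_plus,1.0,1.1,-0.1,-0.9,-0.7,1362,1512
P17,coxi,int_minus,1.2,1.2,0.1,-0.8,0.9,1362,1512
P17,coxi,deficient,6.2,6.2,0.0,-1.8,1.8,1362,1512
P17,ndufb8,positive,79.6,81.2,-1.6,-4.5,1.3,1362,1512
P17,ndufb8,int_plus,7.1,5.9,1.2,-0.6,3.0,1362,1512
P17,ndufb8,int_minus,3.3,3.6,-0.3,-1.6,1.1,1362,1512
P17,ndufb8,deficient,10.0,9.3,0.7,-1.5,2.8,1362,1512
P18,coxi,positive,0.5,0.4,0.1,-0.5,0.6,1012,1689
P18,coxi,int_plus,1.1,0.9,0.1,-0.7,0.9,1012,1689
P18,coxi,int_minus,2.5,1.6,0.9,-0.3,2.0,1012,1689
P18,coxi,deficient,95.9,97.0,-1.1,-2.6,0.4,1012,1689
P18,ndufb8,positive,0.4,0.2,0.2,-0.2,0.7,1012,1689
P18,ndufb8,int_plus,0.5,0.4,0.1,-0.5,0.6,1012,1689
P18,ndufb8,int_minus,4.4,2.2,2.3,0.8,3.2,1012,1689
P18,ndufb8,deficient,94.7,97.2,-2.6,-4.1,-1.0,1012,1689
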