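trait,provenance,mean,se,min,max,cv,letters
FL,GXLZ,1525.52,21.43,1442.72,1635.32,3.97,a
FL,GXFCG,1459.09,45.27,1191.38,1630.81,9.81,a
FL,GXNN,1432.45,23.75,1334.34,1555.94,5.50,ab
FL,GDGZ,1411.77,38.03,1127.74,1547.69,9.33,ab
FL,GDYF,1303.55,70.03,1152.66,1428.27,10.74,b
FL,YNBS,1450.56,35.81,1072.86,1692.28,11.84,a
FL,YNDH,1415.46,24.41,1180.88,1619.33,8.27,ab
FL,YNJH,1398.71,21.27,1100.28,1661.14,9.86,ab
FL,YNMS,1403.86,34.67,1259.07,1554.06,6.98,ab
FL,YNMN,1428.68,31.09,1184.37,1618.10,8.70,ab
FD,GXLZ,32.99,0.40,30.86,34.26,3.47,a
FD,GXFCG,32.11,0.44,29.11,33.39,4.29,ab
FD,GXNN,32.65,0.28,31.51,34.56,2.80,a
FD,GDGZ,32.60,0.38,29.61,34.24,4.08,a
FD,GDYF,31.35,0.35,30.36,32.02,2.25,b
FD,YNBS,32.31,0.32,28.45,35.85,4.73,ab
FD,YNDH,32.57,0.21,30.54,34.27,3.03,a
FD,YNJH,32.38,0.18,28.66,34.20,3.67,ab
FD,YNMS,31.96,0.35,30.24,32.97,3.14,ab
FD,YNMN,32.30,0.25,30.30,33.84,3.11,ab
FL_FD,GXLZ,46.27,0.72,44.18,50.27,4.40,a
FL_FD,GXFCG,45.37,0.98,40.93,48.85,6.81,a
FL_FD,GXNN,43.87,0.57,41.84,47.78,4.30,ab
FL_FD,GDGZ,43.23,0.74,36.96,45.73,5.94,ab
FL_FD,GDYF,41.53,1.89,37.97,44.99,9.10,b
FL_FD,YNBS,44.77,0.77,37.71,49.41,8.24,a
FL_FD,YNDH,43.42,0.59,37.50,50.06,6.55,ab
FL_FD,YNJH,43.15,0.54,36.98,50.55,8.15,ab
FL_FD,YNMS,43.90,0.78,40.96,47.38,5.00,ab
FL_FD,YNMN,44.22,0.86,37.16,50.98,7.82,ab
VL,GXLZ,696.34,33.29,572.87,873.28,13.52,a
VL,GXFCG,656.88,26.47,522.80,802.90,12.74,ab
VL,GXNN,601.42,20.41,521.48,732.25,11.26,b
VL,GDGZ,643.94,19.49,551.55,748.09,10.48,ab
VL,GDYF,676.82,60.44,549.34,823.63,17.86,ab
VL,YNBS,691.06,20.35,547.53,875.98,14.12,a
VL,YNDH,651.15,23.54,491.42,866.51,17.34,ab
VL,YNJH,659.95,12.82,532.67,833.18,12.59,ab
VL,YNMS,654.00,26.61,550.01,787.49,11.51,ab
VL,YNMN,639.87,16.40,551.43,822.21,10.25,ab
VD,GXLZ,176.31,5.97,151.27,195.29,9.58,a
VD,GXFCG,164.43,9.94,108.29,207.51,19.11,ab
VD,GXNN,165.83,6.23,140.70,203.94,12.46,ab
VD,GDGZ,168.49,10.19,120.39,243.96,20.95,ab
VD,GDYF,144.87,12.75,118.55,177.27,17.60,b
VD,YNBS,158.96,5.95,107.95,226.68,17.97,ab
VD,YNDH,162.25,6.13,111.55,231.30,18.11,ab
VD,YNJH,160.13,3.27,99.36,193.57,13.25,ab
VD,YNMS,157.31,7.60,120.70,176.66,13.67,ab
VD,YNMN,165.72,5.31,129.60,213.93,12.81,ab
VL_VD,GXLZ,3.95,0.12,3.57,4.60,8.73,bc
VL_VD,GXFCG,4.06,0.15,3.56,4.83,11.75,bc
VL_VD,GXNN,3.65,0.12,3.06,4.50,10.81,c
VL_VD,GDGZ,3.93,0.19,2.86,4.90,16.33,bc
VL_VD,GDYF,4.68,0.21,4.16,5.17,8.90,a
VL_VD,YNBS,4.41,0.11,3.52,5.64,12.43,ab
VL_VD,YNDH,4.08,0.15,3.28,5.68,17.72,bc
VL_VD,YNJH,4.16,0.09,3.10,5.63,13.27,abc
VL_VD,YNMS,4.22,0.24,3.12,5.19,15.88,ab
VL_VD,YNMN,3.89,0.10,3.33,4.77,10.07,bc
WBD,GXLZ,0.3275,0.0101,0.2886,0.3782,8.74,bc
WBD,GXFCG,0.3389,0.0099,0.2878,0.3896,9.20,abc
WBD,GXNN,0.3274,0.0081,0.2980,0.3820,8.21,bc
WBD,GDGZ,0.3457,0.0067,0.3188,0.3900,6.69,abc
WBD,GDYF,0.3435,0.0160,0.3146,0.3892,9.31,abc
WBD,YNBS,0.3600,0.0046,0.3302,0.4128,6.15,a
WBD,YNDH,0.3253,0.0048,0.2656,0.3660,7.13,c
WBD,YNJH,0.3381,0.0042,0.2960,0.3958,8.14,abc
WBD,YNMS,0.3533,0.0085,0.3252,0.3872,6.83,ab
WBD,YNMN,0.3298,0.0092,0.2606,0.4000,11.13,bc
Cr,GXLZ,50.24,0.89,47.90,53.96,5.04,a
Cr,GXFCG,50.15,0.45,47.44,51.81,2.87,a
Cr,GXNN,52.17,0.70,47.84,56.36,4.43,a
Cr,GDGZ,50.62,0.85,45.17,55.38,5.80,a
Cr,GDYF,51.19,0.62,49.87,52.77,2.43,a
Cr,YNBS,51.90,0.67,45.91,55.79,6.22,a
Cr,YNDH,51.87,0.47,47.93,58.23,4.33,a
Cr,YNJH,52.10,0.47,40.95,61.11,5.87,a
Cr,YNMS,52.62,0.84,50.05,57.39,4.50,a
Cr,YNMN,50.63,0.76,45.73,56.01,6.00,a
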