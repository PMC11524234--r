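trait,provenance,mean,se,min,max,cv,letters
DBH,GXLZ,12.92,0.52,4.10,20.80,28.88,ab
DBH,GXFCG,13.31,0.45,7.00,20.90,24.74,a
DBH,GXNN,13.26,0.52,4.40,20.10,28.84,a
DBH,GDGZ,11.41,0.49,5.60,19.30,28.07,b
DBH,GDYF,12.03,0.56,4.80,20.10,30.12,ab
DBH,YNBS,11.66,0.50,4.20,17.80,27.86,ab
DBH,YNDH,12.20,0.54,3.90,19.80,31.54,ab
DBH,YNJH,13.22,0.44,6.50,18.20,21.94,a
DBH,YNMS,13.01,0.47,5.70,20.80,26.00,ab
DBH,YNMN,12.14,0.55,5.20,19.70,29.86,ab
H,GXLZ,12.01,0.54,1.00,19.00,32.22,abcd
H,GXFCG,12.98,0.44,7.00,19.50,24.79,ab
H,GXNN,13.09,0.46,6.00,19.00,25.64,a
H,GDGZ,10.91,0.51,4.00,17.30,30.44,d
H,GDYF,11.28,0.52,5.00,17.00,29.91,cd
H,YNBS,11.29,0.56,5.00,18.00,32.74,cd
H,YNDH,11.91,0.53,4.00,19.00,31.75,abcd
H,YNJH,12.78,0.46,7.00,18.00,23.64,abc
H,YNMS,12.12,0.48,5.00,18.00,28.60,abcd
H,YNMN,11.43,0.53,5.00,18.00,30.81,bcd
V,GXLZ,0.0907,0.0096,0.0025,0.3033,75.40,ab
V,GXFCG,0.0991,0.0091,0.0127,0.3143,67.23,a
V,GXNN,0.1022,0.0095,0.0043,0.2833,68.04,a
V,GDGZ,0.0647,0.0078,0.0058,0.2378,78.95,b
V,GDYF,0.0745,0.0085,0.0043,0.2236,73.91,ab
V,YNBS,0.0695,0.0080,0.0040,0.2104,75.09,b
V,YNDH,0.0833,0.0094,0.0022,0.2504,80.04,ab
V,YNJH,0.0930,0.0083,0.0109,0.2128,58.79,ab
V,YNMS,0.0890,0.0079,0.0060,0.2249,64.20,ab
V,YNMN,0.0784,0.0096,0.0060,0.2291,81.63,ab
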