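trait,b0,b1,b2,b3,b4,b5,r2,p_value
DBH,-393.1,14.85,4.574,-0.3657,-0.02434,0.01936,0.0195,7.34e-07
H,-169.6,7.012,1.971,-0.2409,-0.01412,0.04008,0.0153,1.68e-05
V,-5.54,0.2083,0.06306,-0.004804,-0.0003198,0.0001185,0.0171,4.73e-06
FL,-16750,145.6,309.1,-7.195,-1.695,2.044,0.0409,0.2709
FD,76.805095,-2.054393,-0.447867,-0.099681,-0.005207,0.06647,0.0226,0.6524
FL_FD,-587.30009,7.92364,10.20365,-0.11231,-0.04611,-0.02193,0.0578,0.1059
VL,-691.3203,-145.7474,58.2785,11.404,0.1355,-3.7184,0.0372,0.3282
VD,-531.15,12.6525,9.5999,-2.3297,-0.1494,0.9469,0.0230,0.6162
VL_VD,25.438914,-1.402947,-0.076717,0.135262,0.005649,-0.047789,0.1181,0.0018
WBD,4.142,-0.3356,-0.002205,0.00756,0.00002628,-0.0000636,0.0272,0.0007
Cr,305.50611,-11.71736,-2.30488,0.06669,0.00115,0.08674,0.0309,0.4412
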