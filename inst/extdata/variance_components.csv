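trait,v_p,v_p_se,v_pb,v_pb_se,v_e,v_e_se,h2,cv_g
DBH,0.47,0.22,0.08,0.07,8.97,0.32,0.67,5.46
H,0.23,0.14,0.26,0.10,5.46,0.19,0.59,4.00
V,9.98e-05,5.91e-05,3.39e-05,2.64e-05,2.17e-03,7.85e-05,0.64,11.83
FL,69.50,533.00,NA,NA,17595.30,2037.00,0.02,0.59
FD,0.00,0.03,NA,NA,1.41,0.16,NA,NA
FL_FD,0.31,0.46,NA,NA,10.03,1.16,0.16,1.26
VL,94.03,277.50,NA,NA,7771.29,900.80,0.07,1.48
VD,0.00,17.78,NA,NA,644.00,74.50,NA,NA
VL_VD,3.52e-02,2.81e-02,NA,NA,0.31,0.03,0.40,4.57
WBD,1.01e-04,7.48e-05,NA,NA,7.35e-04,8.56e-05,0.45,2.96
Cr,0.16,0.31,NA,NA,7.61,0.88,0.11,0.78
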