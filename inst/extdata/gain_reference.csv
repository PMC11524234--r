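trait,overall_mean,overall_se,wood_mean,wood_se,wood_gain,pulp_mean,pulp_se,pulp_gain
DBH,12.52,0.22,13.01,0.47,3.91,13.16,0.12,5.11
H,11.98,0.24,12.12,0.48,1.17,12.69,0.34,5.93
V,0.08,0.00,0.09,0.01,12.50,0.10,0.00,25.00
FL,1422.97,17.67,1403.86,34.67,-1.34,1472.35,27.67,3.47
FD,32.32,0.14,31.96,0.35,-1.11,32.58,0.26,0.80
FL_FD,43.97,0.41,43.90,0.78,-0.16,45.17,0.70,2.73
VL,657.14,8.63,654.00,26.61,-0.48,651.55,27.53,-0.85
VD,162.43,2.60,157.31,7.60,-3.15,168.86,3.75,3.96
VL_VD,4.10,0.09,4.22,0.24,2.93,3.89,0.12,-5.12
WBD,0.34,0.00,0.35,0.01,2.94,0.33,0.00,-2.94
Cr,51.35,0.28,52.62,0.84,2.47,50.85,0.66,-0.97
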