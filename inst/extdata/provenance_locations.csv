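code,latitude,longitude,altitude,annual_mean_temp,min_temp,max_temp,frostless_period,annual_precip
GXLZ,22.36,106.84,269,22.2,0.8,39.9,352,1260
GXFCG,21.77,107.35,235,21.8,1.4,37.8,360,2512
GXNN,22.85,108.40,80,21.7,-2.4,40.4,364,1304.2
GDGZ,23.10,113.21,10,22.1,0.0,39.3,346,1696.5
GDYF,22.10,112.02,346,21.5,-1.0,39.1,345,1670.5
YNBS,25.08,99.16,1670,17.4,-4.2,40.4,283,1710
YNDH,24.08,97.39,780,18.9,-2.9,35.7,299,1544
YNJH,21.02,101.04,552.7,21.0,2.7,41.1,365,1197
YNMS,24.20,98.95,913,19.6,-0.6,36.2,315,1650
YNMN,21.40,101.30,631,21.0,0.5,38.4,331,1540
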