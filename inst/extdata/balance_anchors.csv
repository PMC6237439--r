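culture,n_replicates,co_substrate,fructose,acetate,butyrate,formate,lactate,H2,CO2
RI_mono,4,acetate,-48.8,-20.6,58.5,6.8,3.9,72.2,84.0
FP_mono,3,acetate,-23.1,-13.5,29.8,22.7,1.8,0.2,19.3
BH_mono,3,formate,-19.0,23.0,0.0,-36.1,6.0,31.5,26.0
RI_FP_acetate,2,acetate,-47.7,-18.1,56.3,7.6,4.3,114,85.7
RI_BH_acetate,2,acetate,-46.5,-7.5,53.5,-0.5,2.2,53.0,74.9
RI_BH_none,2,none,-48.0,44.9,27.9,-1.0,5.4,33.1,47.4
FP_BH_acetate,2,acetate,-49.3,41.4,30.7,-1.2,3.9,56.2,54.8
FP_BH_none,1,none,-47.0,62.5,25.5,-1.1,4.5,62.9,63.6
TRI,6,none,-48.9,38.4,32.5,-1.2,7.4,61.9,57.1
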