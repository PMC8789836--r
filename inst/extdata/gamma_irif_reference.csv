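dose_gy,time_min,marker,irif_per_cell,irif_per_cell_se,irif_per_um3,irif_per_um3_se,volume_um3,volume_se,n_cells
0,NA,53BP1,5,4,0.007,0.006,723,100,20
0,NA,pDNA-PKcs,4,4,0.006,0.006,723,100,20
1.9,3,53BP1,32.7,2.6,0.039,0.004,864,55,14
1.9,3,pDNA-PKcs,35.4,2.5,0.043,0.006,864,55,14
1.9,5,53BP1,29.7,3.7,0.044,0.005,685,79,14
1.9,5,pDNA-PKcs,35.9,4.8,0.052,0.005,685,79,14
1.9,10,53BP1,30.5,3.6,0.042,0.009,843,108,20
1.9,10,pDNA-PKcs,35.1,5.1,0.0486,0.011,843,108,20
1.9,30,53BP1,27.7,2.8,0.0292,0.0018,964,111,18
1.9,30,pDNA-PKcs,29.3,2.5,0.0312,0.0013,964,111,18
3.0,3,53BP1,39.5,2.5,0.060,0.004,675,57,18
3.0,3,pDNA-PKcs,43.1,2.5,0.064,0.003,675,57,18
3.0,5,53BP1,35.0,3.0,0.073,0.009,531,65,20
3.0,5,pDNA-PKcs,35.3,2.9,0.073,0.009,531,65,20
3.0,10,53BP1,33.3,2.5,0.060,0.005,567,36,20
3.0,10,pDNA-PKcs,35.2,2.4,0.064,0.005,567,36,20
3.0,30,53BP1,39.2,4.8,0.062,0.006,660,91,18
3.0,30,pDNA-PKcs,39.9,4.7,0.063,0.006,660,91,18
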