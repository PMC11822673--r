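experiment,group,variable,mean,sd,n
aging,MA,total_voids,3.6,1.51,10
aging,MA,total_area_cm2,34.73,13.1,10
aging,MA,pct_area_corners,79.08,13.52,10
aging,MA,pct_large_voids,61.17,30.61,10
aging,O,total_voids,4.16,2.73,31
aging,O,total_area_cm2,48.8,30.03,31
aging,O,pct_area_corners,45.63,24.25,31
aging,O,pct_large_voids,61.51,31.24,31
hfd,NCD,total_voids,2.2,1.81,10
hfd,NCD,total_area_cm2,47.41,16.35,10
hfd,NCD,pct_area_corners,56.46,23.95,10
hfd,NCD,pct_large_voids,97.14,9.04,10
hfd,HFD,total_voids,2,0.71,9
hfd,HFD,total_area_cm2,41.94,17.31,9
hfd,HFD,pct_area_corners,56.58,24.73,9
hfd,HFD,pct_large_voids,85.19,22.73,9
transplant,PBS,total_voids,2.88,2.19,25
transplant,PBS,total_area_cm2,42.56,21.74,25
transplant,PBS,pct_area_corners,46.22,24.12,25
transplant,PBS,pct_large_voids,74.46,35.12,25
transplant,Proliferating,total_voids,2.35,1.43,23
transplant,Proliferating,total_area_cm2,42.21,17.43,23
transplant,Proliferating,pct_area_corners,61.63,15.71,23
transplant,Proliferating,pct_large_voids,85.35,24.74,23
transplant,Senescent,total_voids,3.55,3.46,22
transplant,Senescent,total_area_cm2,40.73,24.08,22
transplant,Senescent,pct_area_corners,54.54,26.16,22
transplant,Senescent,pct_large_voids,70.38,36.71,22
senolytic,NoTx,total_voids,3.04,1.57,11
senolytic,NoTx,total_area_cm2,51.41,35.5,11
senolytic,NoTx,pct_area_corners,50.29,23.93,11
senolytic,NoTx,pct_large_voids,75.12,23.03,11
senolytic,Water,total_voids,4.18,2.63,22
senolytic,Water,total_area_cm2,47.8,23.6,22
senolytic,Water,pct_area_corners,44.82,19.1,22
senolytic,Water,pct_large_voids,59.36,23.9,22
senolytic,Vehicle,total_voids,3.79,3.01,19
senolytic,Vehicle,total_area_cm2,50.73,23.36,19
senolytic,Vehicle,pct_area_corners,51.11,19.83,19
senolytic,Vehicle,pct_large_voids,72.82,26.51,19
senolytic,DQ,total_voids,4.06,2.59,25
senolytic,DQ,total_area_cm2,49.86,23.51,25
senolytic,DQ,pct_area_corners,43.06,26.01,25
senolytic,DQ,pct_large_voids,68.5,32.21,25
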