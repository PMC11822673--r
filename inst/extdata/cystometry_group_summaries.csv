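experiment,group,variable,mean,sd,n
aging,MA,Pbase,7.03,1.61,10
aging,MA,Pthresh,16.51,3.85,10
aging,MA,Pmax,53.01,4.78,10
aging,MA,Pend,25.32,3.84,10
aging,MA,IVI,172.86,53.86,10
aging,MA,voided_volume,0.07,0.02,10
aging,MA,flow_rate,0.03,0.01,10
aging,O,Pbase,7.46,1.94,18
aging,O,Pthresh,20.33,8.17,18
aging,O,Pmax,44.04,8.18,18
aging,O,Pend,27.67,6.82,18
aging,O,IVI,199.68,76.47,18
aging,O,voided_volume,0.07,0.03,18
aging,O,flow_rate,0.03,0.01,18
hfd,NCD,Pbase,9.89,2.55,8
hfd,NCD,Pthresh,22.18,7.73,8
hfd,NCD,Pmax,52.85,5.43,8
hfd,NCD,Pend,27.96,5.81,8
hfd,NCD,IVI,106.47,27.6,8
hfd,NCD,voided_volume,0.05,0.01,8
hfd,NCD,flow_rate,0.02,0.01,8
hfd,HFD,Pbase,9.68,1.55,7
hfd,HFD,Pthresh,19.37,3.98,7
hfd,HFD,Pmax,46.26,6.08,7
hfd,HFD,Pend,26.95,5.22,7
hfd,HFD,IVI,113.06,30.66,7
hfd,HFD,voided_volume,0.04,0.01,7
hfd,HFD,flow_rate,0.02,0.02,7
hfd_dq,HFD,Pbase,8.63,1.91,7
hfd_dq,HFD,Pthresh,17.26,1.8,7
hfd_dq,HFD,Pmax,42.51,3.96,7
hfd_dq,HFD,Pend,26.3,4.37,7
hfd_dq,HFD,IVI,166.45,56.17,7
hfd_dq,HFD,voided_volume,0.06,0.01,7
hfd_dq,HFD,flow_rate,0.01,0.0,7
hfd_dq,HFD_DQ,Pbase,10.57,2.74,6
hfd_dq,HFD_DQ,Pthresh,20.59,4.94,6
hfd_dq,HFD_DQ,Pmax,44.84,6.46,6
hfd_dq,HFD_DQ,Pend,28.61,4.21,6
hfd_dq,HFD_DQ,IVI,122.23,49.48,6
hfd_dq,HFD_DQ,voided_volume,0.04,0.02,6
hfd_dq,HFD_DQ,flow_rate,0.01,0.01,6
transplant,PBS,Pbase,5.92,1.47,9
transplant,PBS,Pthresh,17.11,2.98,9
transplant,PBS,Pmax,53.04,3.7,9
transplant,PBS,Pend,21.81,2.74,9
transplant,PBS,IVI,188.94,64.94,9
transplant,PBS,voided_volume,0.07,0.02,9
transplant,PBS,flow_rate,0.03,0.01,9
transplant,Proliferating,Pbase,5.84,1.2,10
transplant,Proliferating,Pthresh,15.96,5.3,10
transplant,Proliferating,Pmax,49.92,6.2,10
transplant,Proliferating,Pend,23.05,5.17,10
transplant,Proliferating,IVI,181.18,57.11,10
transplant,Proliferating,voided_volume,0.07,0.02,10
transplant,Proliferating,flow_rate,0.03,0.01,10
transplant,Senescent,Pbase,6.48,1.47,11
transplant,Senescent,Pthresh,16.21,5.39,11
transplant,Senescent,Pmax,48.19,3.05,11
transplant,Senescent,Pend,25.25,6.86,11
transplant,Senescent,IVI,188.38,68.14,11
transplant,Senescent,voided_volume,0.08,0.03,11
transplant,Senescent,flow_rate,0.03,0.01,11
senolytic,NoTx,Pbase,6.02,1.71,8
senolytic,NoTx,Pthresh,16.97,6.74,8
senolytic,NoTx,Pmax,43.42,6.84,8
senolytic,NoTx,Pend,27.67,9.14,8
senolytic,NoTx,IVI,172.63,76.16,8
senolytic,NoTx,voided_volume,0.06,0.03,8
senolytic,NoTx,flow_rate,0.02,0.01,8
senolytic,Water,Pbase,5.32,1.95,9
senolytic,Water,Pthresh,13.95,2.28,9
senolytic,Water,Pmax,41.79,7.04,9
senolytic,Water,Pend,24.34,6.2,9
senolytic,Water,IVI,191.3,44.46,9
senolytic,Water,voided_volume,0.07,0.02,9
senolytic,Water,flow_rate,0.03,0.01,9
senolytic,Vehicle,Pbase,5.38,2.81,17
senolytic,Vehicle,Pthresh,17.66,6.17,17
senolytic,Vehicle,Pmax,43.46,3.89,17
senolytic,Vehicle,Pend,23.6,6.19,17
senolytic,Vehicle,IVI,190.77,56.33,17
senolytic,Vehicle,voided_volume,0.07,0.02,17
senolytic,Vehicle,flow_rate,0.02,0.01,17
senolytic,DQ,Pbase,6.5,2.85,16
senolytic,DQ,Pthresh,18.11,7.29,16
senolytic,DQ,Pmax,43.68,7.51,16
senolytic,DQ,Pend,23.4,4.78,16
senolytic,DQ,IVI,185.35,80.35,16
senolytic,DQ,voided_volume,0.07,0.03,16
senolytic,DQ,flow_rate,0.02,0.01,16
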