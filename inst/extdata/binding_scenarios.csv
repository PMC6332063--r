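host_id,guest_id,substituent,n_walls,esp,K,K_err,method,minus_dG_printed,minus_ddG_printed,ddG_err_printed
1a,2a,octamethyl,0,,72.2,14,NMR,2.53,,
1b,2a,OMe,2,-20.7,5150,1300,NMR,5.06,2.51,0.19
1c,2a,N3,2,-12.9,3870,400,NMR,4.89,2.36,0.12
1d,2a,NO2,2,-2.0,4720,900,NMR,5.01,2.52,0.16
1e,2a,OMe,4,-20.7,141000,10000,ITC,7.02,4.49,0.12
1f,2a,NO2,4,-2.0,106000,10000,ITC,6.85,4.32,0.12
1a,2b,octamethyl,0,,8.91,1.8,NMR,1.30,,
1b,2b,OMe,2,-20.7,82.1,9,NMR,2.61,1.32,0.13
1c,2b,N3,2,-12.9,70.0,8,NMR,2.52,1.22,0.14
1d,2b,NO2,2,-2.0,79.8,16,NMR,2.59,1.30,0.17
1e,2b,OMe,4,-20.7,96.0,9,NMR,2.70,1.41,0.13
1f,2b,NO2,4,-2.0,257,30,NMR,3.29,2.00,0.14
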