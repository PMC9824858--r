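sample_id,shape,dim1_cm,dim2_cm,dim3_cm,timepoint_min,mass_g,velocity_m_s
cyl6,cylinder,6,6,NA,0,102.6,4710
cyl6,cylinder,6,6,NA,10,106.6,4350
cyl6,cylinder,6,6,NA,20,115.8,3860
cyl6,cylinder,6,6,NA,30,117.2,3480
cyl6,cylinder,6,6,NA,40,120.9,3200
cyl6,cylinder,6,6,NA,60,125.9,3040
cyl6,cylinder,6,6,NA,240,132,2780
cyl6,cylinder,6,6,NA,300,133.7,2760
cyl6,cylinder,6,6,NA,1320,144.4,2380
cyl6,cylinder,6,6,NA,1440,145,2340
cyl6,cylinder,6,6,NA,1800,148.7,2280
cyl6,cylinder,6,6,NA,1920,150.1,1950
cyl6,cylinder,6,6,NA,2880,154.5,1820
cyl6,cylinder,6,6,NA,10080,169.8,1630
cyl6,cylinder,6,6,NA,12960,173.6,1500
cyl7,cylinder,7,7,NA,0,111.2,4950
cyl7,cylinder,7,7,NA,10,122.6,4420
cyl7,cylinder,7,7,NA,20,125.7,3950
cyl7,cylinder,7,7,NA,30,127.3,3690
cyl7,cylinder,7,7,NA,40,129.7,3660
cyl7,cylinder,7,7,NA,60,132.9,3500
cyl7,cylinder,7,7,NA,240,141.7,2900
cyl7,cylinder,7,7,NA,300,144,2880
cyl7,cylinder,7,7,NA,1320,157,2280
cyl7,cylinder,7,7,NA,1440,160,2110
cyl7,cylinder,7,7,NA,1800,165.4,2330
cyl7,cylinder,7,7,NA,1920,166,2030
cyl7,cylinder,7,7,NA,2880,172,1700
cyl7,cylinder,7,7,NA,10080,191.5,1560
cyl7,cylinder,7,7,NA,12960,196.7,1520
cyl10,cylinder,10,10,NA,0,294,5140
cyl10,cylinder,10,10,NA,10,311,4550
cyl10,cylinder,10,10,NA,20,320.8,4430
cyl10,cylinder,10,10,NA,30,328.7,4340
cyl10,cylinder,10,10,NA,40,331.4,4120
cyl10,cylinder,10,10,NA,60,339.2,3970
cyl10,cylinder,10,10,NA,240,366.2,3770
cyl10,cylinder,10,10,NA,300,373.1,3680
cyl10,cylinder,10,10,NA,1320,410.2,2840
cyl10,cylinder,10,10,NA,1440,415,2770
cyl10,cylinder,10,10,NA,1800,426.1,2600
cyl10,cylinder,10,10,NA,1920,429.2,2490
cyl10,cylinder,10,10,NA,2880,448.2,2160
cyl10,cylinder,10,10,NA,10080,494.1,1740
cyl10,cylinder,10,10,NA,12960,506.7,1640
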