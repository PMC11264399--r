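group,wave,item,n,mean,sd,skewness,kurtosis
mothers,T1,EPDS1,869,0.114,0.371,3.850,17.948
mothers,T1,EPDS2,869,0.119,0.379,3.753,16.875
mothers,T1,EPDS3,869,0.532,0.720,1.177,0.662
mothers,T1,EPDS4,869,0.667,0.786,0.790,-0.534
mothers,T1,EPDS5,869,0.192,0.493,2.808,8.213
mothers,T1,EPDS6,869,0.648,0.681,0.640,-0.419
mothers,T1,EPDS7,869,0.160,0.474,3.257,10.949
mothers,T1,EPDS8,867,0.405,0.611,1.420,1.773
mothers,T1,EPDS9,867,0.175,0.410,2.203,4.113
mothers,T1,EPDS10,867,0.012,0.135,15.584,295.739
mothers,T2,EPDS1,767,0.098,0.342,3.921,17.427
mothers,T2,EPDS2,767,0.091,0.318,3.900,18.102
mothers,T2,EPDS3,767,0.567,0.750,1.141,0.550
mothers,T2,EPDS4,767,0.643,0.745,0.741,-0.635
mothers,T2,EPDS5,767,0.173,0.454,2.849,8.556
mothers,T2,EPDS6,767,0.590,0.662,0.712,-0.446
mothers,T2,EPDS7,767,0.163,0.464,3.152,10.441
mothers,T2,EPDS8,767,0.396,0.564,1.162,0.850
mothers,T2,EPDS9,765,0.134,0.363,2.638,6.406
mothers,T2,EPDS10,765,0.017,0.139,8.880,87.352
mothers,T3,EPDS1,736,0.124,0.386,3.426,12.682
mothers,T3,EPDS2,736,0.110,0.358,3.603,14.635
mothers,T3,EPDS3,736,0.563,0.728,1.057,0.288
mothers,T3,EPDS4,736,0.641,0.762,0.855,-0.275
mothers,T3,EPDS5,736,0.178,0.480,2.881,8.241
mothers,T3,EPDS6,736,0.671,0.708,0.613,-0.641
mothers,T3,EPDS7,736,0.177,0.499,3.216,11.056
mothers,T3,EPDS8,735,0.415,0.584,1.156,0.768
mothers,T3,EPDS9,735,0.178,0.427,2.345,4.929
mothers,T3,EPDS10,735,0.016,0.137,9.175,93.482
fathers,T1,EPDS1,579,0.100,0.333,3.759,17.108
fathers,T1,EPDS2,579,0.123,0.382,3.645,16.047
fathers,T1,EPDS3,579,0.468,0.668,1.251,0.867
fathers,T1,EPDS4,579,0.473,0.691,3.566,0.330
fathers,T1,EPDS5,579,0.105,0.354,2.808,12.906
fathers,T1,EPDS6,579,0.565,0.689,0.881,-0.188
fathers,T1,EPDS7,579,0.192,0.499,2.860,8.517
fathers,T1,EPDS8,578,0.304,0.534,1.686,2.720
fathers,T1,EPDS9,578,0.042,0.216,5.599,34.008
fathers,T1,EPDS10,578,0.014,0.144,11.468,140.959
fathers,T2,EPDS1,551,0.089,0.327,4.558,26.936
fathers,T2,EPDS2,549,0.095,0.350,4.468,24.169
fathers,T2,EPDS3,549,0.430,0.649,1.309,0.842
fathers,T2,EPDS4,549,0.455,0.678,1.219,0.315
fathers,T2,EPDS5,549,0.080,0.278,3.353,10.397
fathers,T2,EPDS6,549,0.525,0.682,1.002,0.047
fathers,T2,EPDS7,547,0.144,0.431,3.237,10.805
fathers,T2,EPDS8,545,0.347,0.565,1.453,1.467
fathers,T2,EPDS9,545,0.031,0.174,5.409,27.352
fathers,T2,EPDS10,545,0.011,0.121,12.295,167.176
fathers,T3,EPDS1,519,0.112,0.372,3.978,19.265
fathers,T3,EPDS2,517,0.130,0.432,4.160,20.266
fathers,T3,EPDS3,517,0.383,0.613,1.516,1.863
fathers,T3,EPDS4,517,0.385,0.654,1.666,2.245
fathers,T3,EPDS5,517,0.093,0.334,3.843,15.218
fathers,T3,EPDS6,516,0.494,0.664,1.041,0.065
fathers,T3,EPDS7,516,0.126,0.401,3.527,13.408
fathers,T3,EPDS8,516,0.331,0.544,1.463,1.615
fathers,T3,EPDS9,516,0.025,0.169,7.249,57.832
fathers,T3,EPDS10,516,0.014,0.131,10.833,130.392
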