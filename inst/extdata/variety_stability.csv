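trait,variety,mean,sensitivity
yield,Balado,7.98,1.151
yield,Gerald,8.24,0.982
yield,Mascani,8.18,1.020
yield,Tardis,8.25,0.844
grain_number,Balado,19.31,1.218
grain_number,Gerald,22.16,1.078
grain_number,Mascani,18.05,0.912
grain_number,Tardis,19.74,0.785
groat_content,Balado,70.82,1.744
groat_content,Gerald,72.81,1.096
groat_content,Mascani,76.78,0.525
groat_content,Tardis,72.23,0.590
hullability,Balado,83.64,1.522
hullability,Gerald,87.75,1.052
hullability,Mascani,98.54,0.129
hullability,Tardis,81.38,1.290
hectoliter_weight,Balado,48.09,1.085
hectoliter_weight,Gerald,52.16,0.998
hectoliter_weight,Mascani,52.22,0.926
hectoliter_weight,Tardis,49.16,0.990
tgw,Balado,41.81,1.381
tgw,Gerald,37.44,0.988
tgw,Mascani,45.39,0.799
tgw,Tardis,41.90,0.808
width,Balado,3.16,1.316
width,Gerald,3.09,0.952
width,Mascani,3.23,0.817
width,Tardis,3.17,0.901
length,Balado,11.62,1.030
length,Gerald,10.53,0.866
length,Mascani,11.23,1.066
length,Tardis,11.89,1.038
roundness,Balado,0.273,0.986
roundness,Gerald,0.294,0.890
roundness,Mascani,0.290,1.142
roundness,Tardis,0.268,0.982
oil,Balado,7.53,1.450
oil,Gerald,7.36,0.786
oil,Mascani,6.70,0.906
oil,Tardis,7.72,0.817
protein,Balado,9.92,1.056
protein,Gerald,9.54,0.956
protein,Mascani,9.76,1.011
protein,Tardis,10.13,0.977
beta_glucan,Balado,4.76,1.101
beta_glucan,Gerald,3.57,0.986
beta_glucan,Mascani,4.26,1.068
beta_glucan,Tardis,4.07,0.843
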