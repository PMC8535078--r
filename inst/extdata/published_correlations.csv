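trait,covariate,r,stars
yield,rain_dec_apr,-0.042,
yield,rain_jun_jul,-0.768,***
yield,temp_mar,-0.422,
yield,temp_jul,0.404,
groat_content,rain_dec_apr,-0.441,*
groat_content,rain_jun_jul,-0.137,
groat_content,temp_mar,-0.121,
groat_content,temp_jul,-0.062,
hullability,rain_dec_apr,-0.169,
hullability,rain_jun_jul,0.803,***
hullability,temp_mar,0.612,**
hullability,temp_jul,-0.481,*
hectoliter_weight,rain_dec_apr,-0.234,
hectoliter_weight,rain_jun_jul,-0.611,**
hectoliter_weight,temp_mar,-0.414,
hectoliter_weight,temp_jul,0.110,
grain_number,rain_dec_apr,0.039,
grain_number,rain_jun_jul,-0.698,***
grain_number,temp_mar,-0.339,
grain_number,temp_jul,0.492,*
tgw,rain_dec_apr,-0.222,
tgw,rain_jun_jul,-0.065,
tgw,temp_mar,-0.116,
tgw,temp_jul,-0.266,
width,rain_dec_apr,-0.268,
width,rain_jun_jul,0.313,
width,temp_mar,0.164,
width,temp_jul,-0.531,*
length,rain_dec_apr,-0.059,
length,rain_jun_jul,-0.539,*
length,temp_mar,-0.634,**
length,temp_jul,0.297,
roundness,rain_dec_apr,-0.047,
roundness,rain_jun_jul,0.607,**
roundness,temp_mar,0.634,**
roundness,temp_jul,0.472,*
protein,rain_dec_apr,-0.727,***
protein,rain_jun_jul,-0.002,
protein,temp_mar,0.015,
protein,temp_jul,0.080,
beta_glucan,rain_dec_apr,0.260,
beta_glucan,rain_jun_jul,-0.846,***
beta_glucan,temp_mar,-0.553,**
beta_glucan,temp_jul,0.605,**
oil,rain_dec_apr,0.109,
oil,rain_jun_jul,-0.031,
oil,temp_mar,0.187,
oil,temp_jul,-0.139,
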