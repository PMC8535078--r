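environment,site,latitude,longitude,sowing_date,harvest_date,rain_dec_apr,rain_jun_jul,temp_mar,temp_jul,spring_sown
1,Gogerddan,52.43,-4.02,2011-09-28,2012-08-09,387,273,8.0,13.9,FALSE
2,Gogerddan,52.43,-4.02,2012-10-23,2013-08-18,426,91,2.9,16.6,FALSE
3,Gogerddan,52.43,-4.02,2013-09-25,2014-07-24,574,96,6.8,15.7,FALSE
4,Lydbury,52.45,-2.94,2011-09-30,2012-08-22,270,211,7.9,14.3,FALSE
5,Lydbury,52.45,-2.94,2013-10-08,2014-08-20,316,84,6.4,16.2,FALSE
6,Bidney,52.20,-2.87,2010-10-15,2011-08-17,145,105,6.1,14.4,FALSE
7,Rosemaund,52.08,-2.39,2011-10-06,2012-09-05,325,249,8.1,14.8,FALSE
8,Rosemaund,51.97,-2.62,2013-02-06,2013-09-03,,56,2.4,17.9,TRUE
9,Rosemaund,51.98,-2.60,2013-09-30,2014-07-31,555,88,6.9,16.9,FALSE
10,ADAS Rosemaund,52.09,-2.39,2010-09-28,2011-08-13,149,93,6.6,15.0,FALSE
11,ADAS Rosemaund,52.09,-2.39,2011-09-27,2012-09-06,325,249,8.1,14.8,FALSE
12,ORC Elm Farm,52.36,1.35,2010-10-19,2011-08-03,131,126,6.4,15.3,FALSE
13,ORC Elm Farm,52.36,1.35,2011-10-12,2012-08-22,275,168,8.1,16.0,FALSE
14,ORC Elm Farm,52.36,1.35,2012-10-16,2013-08-24,292,35,2.7,17.6,FALSE
15,Glenrothes,56.19,-3.11,2011-09-28,2012-08-24,205,260,7.0,12.5,FALSE
16,Glenrothes,56.19,-3.11,2012-10-02,2013-08-14,317,90,1.4,15.4,FALSE
17,Glenrothes,56.19,-3.11,2013-09-26,2014-08-04,360,105,5.2,14.8,FALSE
18,Devon,50.27,-3.76,2011-10-03,2012-08-28,420,275,9.0,15.0,FALSE
19,Devon,50.27,-3.76,2012-10-20,2013-08-13,442,43,5.3,17.2,FALSE
20,Devon,50.27,-3.76,2013-10-07,2014-07-31,565,120,8.3,17.2,FALSE
21,Essex,51.58,0.41,2011-10-06,2012-08-16,218,193,8.5,16.0,FALSE
22,Essex,51.58,0.41,2013-10-05,2014-07-22,232,94,8.0,17.7,FALSE
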