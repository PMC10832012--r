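structure,metric,unit,mean_wm,sd_wm,mean_wom,sd_wom,delta_printed,p_printed
PeritonealCavity,Davg,Gy,16.1,6.0,18.8,6.3,-2.6,0.033
PeritonealCavity,V15Gy,cc,497.7,167.3,669.2,253.6,-171.5,0.003
PeritonealCavity,V45Gy,cc,33.2,33.7,45.4,28.4,-12.2,0.029
Rectum,Davg,Gy,35.2,4.8,37.5,4.0,-2.3,0.040
Rectum,V50Gy,percent,19.9,6.5,23.4,6.0,-3.5,0.042
Rectum,V60Gy,percent,10.9,4.9,14.8,4.1,-3.9,0.001
Rectum,V70Gy,percent,5.4,3.3,7.7,2.6,-2.4,0.001
Bladder,Davg,Gy,34.1,7.2,37.3,4.4,-3.2,0.039
Bladder,V60Gy,percent,10.4,7.0,11.1,5.3,-0.6,0.253
Bladder,V70Gy,percent,5.9,3.8,6.5,3.3,-0.6,0.296
AnalCanal,Davg,Gy,14.6,6.8,18.2,7.1,-3.6,0.043
Sigmoid,Davg,Gy,33.5,6.9,36.3,5.2,-2.8,0.152
FemoralHeadRight,Davg,Gy,17.9,4.0,17.5,3.6,0.4,0.723
FemoralHeadLeft,Davg,Gy,17.1,4.0,17.1,3.2,0.0,0.994
PenileBulb,Davg,Gy,29.0,22.6,35.8,22.4,-6.8,0.180
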