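honey_type,temperature_C,time_min,mean,sd,n
sunflower,CONTROL,0,18.5,0.3,3
sunflower,40,60,20.2,1.5,3
sunflower,60,60,16.2,1.0,3
sunflower,80,60,17.6,0.2,3
sunflower,100,60,40.3,0.8,3
sunflower,40,120,17.3,1.3,3
sunflower,60,120,20.5,0.7,3
sunflower,80,120,31.8,1.3,3
sunflower,100,120,155.1,2.7,3
sunflower,40,180,18.4,1.6,3
sunflower,60,180,19.9,1.8,3
sunflower,80,180,37.2,0.6,3
sunflower,100,180,241.5,7.4,3
sunflower,40,240,17.5,1.4,3
sunflower,60,240,19.5,2.0,3
sunflower,80,240,52.0,2.7,3
sunflower,100,240,463.6,28.3,3
bastard_indigo,CONTROL,0,14.7,1.6,3
bastard_indigo,40,60,14.1,2.8,3
bastard_indigo,60,60,18.0,2.3,3
bastard_indigo,80,60,11.9,1.1,3
bastard_indigo,100,60,16.7,0.9,3
bastard_indigo,40,120,15.1,3.5,3
bastard_indigo,60,120,15.8,0.6,3
bastard_indigo,80,120,14.3,1.0,3
bastard_indigo,100,120,81.4,4.0,3
bastard_indigo,40,180,15.7,1.1,3
bastard_indigo,60,180,21.1,3.5,3
bastard_indigo,80,180,19.8,0.6,3
bastard_indigo,100,180,146.4,2.3,3
bastard_indigo,40,240,12.9,1.4,3
bastard_indigo,60,240,13.7,1.3,3
bastard_indigo,80,240,28.2,1.1,3
bastard_indigo,100,240,306.0,17.8,3
acacia,CONTROL,0,7.0,0.4,3
acacia,40,60,9.1,1.3,3
acacia,60,60,7.7,0.3,3
acacia,80,60,8.0,0.4,3
acacia,100,60,16.1,1.7,3
acacia,40,120,8.0,0.6,3
acacia,60,120,8.8,1.4,3
acacia,80,120,13.3,0.9,3
acacia,100,120,44.7,4.3,3
acacia,40,180,8.6,1.0,3
acacia,60,180,9.6,0.3,3
acacia,80,180,12.2,0.8,3
acacia,100,180,89.1,2.8,3
acacia,40,240,10.0,1.1,3
acacia,60,240,9.6,0.9,3
acacia,80,240,18.8,2.4,3
acacia,100,240,211.6,5.0,3
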