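parameter,region,mean,sd,n,ci_low,ci_high,absvar_mean,absvar_sd,cv_intra,ev_intra,cv_inter,ev_inter
cmrglu,thalamus,20.6,10.1,12,0.0,42.8,42.8,28.5,45.8,86,18.6,14
cmrglu,globus_pallidum,19.5,9.3,12,0.0,40.0,34.2,27.3,39.5,67,27.7,33
cmrglu,caudate,24.9,10.8,12,1.2,48.6,41.8,25.7,41.1,89,14.3,11
cmrglu,putamen,26.2,10.9,12,2.2,50.3,42.3,22.0,38.1,82,17.8,18
cmrglu,cortex,19.4,8.2,12,1.5,37.5,39.9,24.1,38.0,80,18.9,20
cmrglu,midbrain,20.4,9.5,12,0.0,41.3,37.1,29.2,43.5,86,17.6,14
cmrglu,pons,15.8,6.9,12,0.7,30.9,25.4,29.2,38.1,75,22.0,25
cmrglu,cerebellum,21.1,9.2,12,0.8,41.5,33.2,25.6,36.0,65,26.1,35
cmrglu,frontal_cortex,26.3,11.1,12,2.0,50.6,40.4,26.8,40.1,90,13.1,10
cmrglu,occipital_cortex,17.0,9.0,12,0.0,36.8,38.3,29.6,46.2,75,26.6,25
suv,thalamus,2.5,0.5,12,1.4,3.5,18.9,16.4,18.5,93,5.2,7
suv,globus_pallidum,2.2,0.4,12,1.3,3.1,20.2,15.3,18.7,90,6.3,10
suv,caudate,2.7,0.5,12,1.5,3.8,16.4,16.4,17.4,76,9.7,24
suv,putamen,2.8,0.5,12,1.7,3.8,16.1,15.7,16.5,90,5.4,10
suv,cortex,2.2,0.3,12,1.5,2.9,16.3,12.5,14.8,94,3.8,6
suv,midbrain,2.3,0.4,12,1.4,3.3,18.5,16.7,17.9,100,0.0,0
suv,pons,1.9,0.3,12,1.3,2.6,19.0,15.4,16.6,100,0.0,0
suv,cerebellum,2.3,0.4,12,1.6,3.1,19.4,10.9,15.8,100,0.0,0
suv,frontal_cortex,2.8,0.5,12,1.5,4.0,16.3,16.6,17.6,76,9.9,24
suv,occipital_cortex,2.1,0.4,12,1.2,3.0,20.5,18.9,21.4,100,0.0,0
suvr_pons,thalamus,1.3,0.1,12,1.1,1.5,11.4,8.4,10.2,100,0.0,0
suvr_pons,globus_pallidum,1.1,0.1,12,0.9,1.3,9.5,9.9,9.9,99,0.9,0.8
suvr_pons,caudate,1.4,0.2,12,1.0,1.8,13.0,12.8,13.3,100,0.0,0
suvr_pons,putamen,1.4,0.1,12,1.2,1.7,11.8,11.6,11.8,100,0.0,0
suvr_pons,cortex,1.1,0.1,12,0.9,1.4,10.3,11.3,10.9,100,0.0,0
suvr_pons,midbrain,1.2,0.1,12,1.0,1.4,9.1,6.7,7.9,100,0.0,0
suvr_pons,cerebellum,1.2,0.1,12,1.0,1.4,6.8,6.7,6.5,99,0.3,0.1
suvr_pons,frontal_cortex,1.4,0.2,12,1.0,1.8,13.9,14.6,15.2,100,0.0,0
suvr_pons,occipital_cortex,1.1,0.1,12,0.9,1.3,10.5,8.8,9.7,100,0.0,0
suvr_cerebellum,thalamus,1.0,0.1,12,0.8,1.2,8.7,4.5,6.8,96,1.3,4
suvr_cerebellum,globus_pallidum,0.9,0.1,12,0.7,1.1,6.8,4.9,5.9,80,3.0,20
suvr_cerebellum,caudate,1.1,0.1,12,0.9,1.4,9.8,7.5,8.5,84,3.7,16
suvr_cerebellum,putamen,1.2,0.1,12,1.0,1.4,8.6,6.8,7.5,98,0.9,2
suvr_cerebellum,cortex,0.9,0.1,12,0.7,1.1,7.1,5.9,6.3,100,0.0,0
suvr_cerebellum,midbrain,1.0,0.1,12,0.8,1.2,6.4,5.0,5.7,92,1.6,8
suvr_cerebellum,pons,0.8,0.1,12,0.6,1.0,6.8,6.7,6.4,96,1.2,4
suvr_cerebellum,frontal_cortex,1.2,0.1,12,1.0,1.4,10.7,8.2,9.5,78,5.1,22
suvr_cerebellum,occipital_cortex,0.9,0.1,12,0.7,1.1,9.8,7.2,8.5,100,0.0,0
suv_gly,thalamus,12.2,4.6,12,2.1,22.4,27.8,31.4,39.4,100,0.0,0
suv_gly,globus_pallidum,10.9,4.1,12,1.9,19.8,27.3,30.9,38.8,100,0.0,0
suv_gly,caudate,13.3,4.6,12,3.2,23.5,27.0,31.0,36.8,100,0.0,0
suv_gly,putamen,13.8,4.7,12,3.5,24.2,26.2,30.8,36.2,100,0.0,0
suv_gly,cortex,10.9,3.5,12,3.2,18.6,24.9,29.1,33.8,100,0.0,0
suv_gly,midbrain,11.7,4.2,12,2.4,21.0,26.9,30.7,38.2,100,0.0,0
suv_gly,pons,9.6,3.1,12,2.8,16.3,24.1,29.2,33.8,100,0.0,0
suv_gly,cerebellum,11.6,3.8,12,3.2,20.0,22.8,27.6,33.0,100,0.0,0
suv_gly,frontal_cortex,13.7,4.6,12,3.5,23.8,27.9,30.3,36.2,100,0.0,0
suv_gly,occipital_cortex,10.5,4.3,12,1.0,19.9,26.7,35.1,43.0,100,0.0,0
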