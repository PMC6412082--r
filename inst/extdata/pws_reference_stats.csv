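measure,cohort,group,n,mean,sd,lo,hi,units,source,note
age,1,PWS,20,23.1,2.4,19.8,27.7,years,summary_table,median-based P printed 0.74 in the summary table but 0.73 in the results text
age,1,Control,40,22.9,2.2,19.6,29.0,years,summary_table,
male_count,1,PWS,20,14,NA,NA,NA,count,summary_table,70.0% male
male_count,1,Control,40,26,NA,NA,NA,count,summary_table,65.0% male
bmi,1,PWS,20,30.1,7.2,21.5,47.7,kg/m2,summary_table,
bmi,1,Control,40,24.1,3.8,19.2,34.2,kg/m2,summary_table,
iq,1,PWS,20,63.1,11.9,48,95,score,summary_table,
iq,1,Control,40,112.9,11.2,81,132,score,summary_table,
brainpad,1,PWS,20,8.74,9.14,NA,NA,years,results,
brainpad,1,Control,40,1.50,7.42,NA,NA,years,results,
wm_volume,1,PWS,20,0.480,0.083,NA,NA,L,volumes_table,printed under a cm^3 label but litre-scale values
wm_volume,1,Control,40,0.478,0.070,NA,NA,L,volumes_table,printed under a cm^3 label but litre-scale values
gm_volume,1,PWS,20,0.662,0.106,NA,NA,L,volumes_table,printed under a cm^3 label but litre-scale values
gm_volume,1,Control,40,0.703,0.104,NA,NA,L,volumes_table,printed under a cm^3 label but litre-scale values
csf_volume,1,PWS,20,0.233,NA,0.198,0.278,L,volumes_table,median with IQR printed in lo/hi
csf_volume,1,Control,40,0.238,NA,0.187,0.317,L,volumes_table,median with IQR printed in lo/hi
brainpad,2,Control,95,0.84,6.48,NA,NA,years,results,
brainpad,2,Control,95,0.84,6.52,NA,NA,years,abstract,same summary with SD printed 6.52 in the abstract
age,2,Control,95,34.0,10.2,19.9,55.5,years,summary_table,
bmi,2,Control,95,28.7,6.6,19.1,53.1,kg/m2,summary_table,
predicted_age,2,SNORD116,1,37.36,NA,NA,NA,years,results,single subject with SNORD116 microdeletion
chronological_age,2,SNORD116,1,24.49,NA,NA,NA,years,results,single subject with SNORD116 microdeletion
brainpad,2,SNORD116,1,12.87,NA,NA,NA,years,results,predicted minus chronological age
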