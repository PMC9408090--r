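condition,measure,mean_high,mean_low,excess,cost_per_worker,stars
poor_sleep,absenteeism,2.07,1.04,1.03,1383.53,
poor_sleep,presenteeism,4.64,2.40,2.24,3008.84,**
poor_sleep,total,6.43,3.36,3.07,4123.72,*
risky_alcohol,absenteeism,1.75,1.68,0.07,94.03,
risky_alcohol,presenteeism,4.12,3.70,0.42,564.16,
risky_alcohol,total,5.71,5.14,0.57,765.64,
smoking,absenteeism,1.99,1.60,0.39,523.86,
smoking,presenteeism,5.70,3.18,2.52,3384.94,**
smoking,total,7.37,4.61,2.77,3720.75,*
poor_diet,absenteeism,1.77,0.07,1.70,2283.49,
poor_diet,presenteeism,3.92,1.88,2.04,2740.19,
poor_diet,total,5.47,1.94,3.53,4741.61,
weight_problem,absenteeism,1.77,1.51,0.26,349.24,
weight_problem,presenteeism,4.02,3.32,0.70,940.26,
weight_problem,total,5.56,4.69,0.86,1155.18,
insufficient_pa,absenteeism,2.73,1.32,1.41,1893.96,*
insufficient_pa,presenteeism,5.13,3.37,1.76,2364.09,
insufficient_pa,total,7.52,4.54,2.98,4002.83,*
poor_physical_health,absenteeism,4.23,1.46,2.77,3720.75,*
poor_physical_health,presenteeism,11.71,3.08,8.63,11592.09,***
poor_physical_health,total,15.11,4.40,10.71,14386.01,***
psychological_distress,absenteeism,3.08,1.01,2.07,2789.49,**
psychological_distress,presenteeism,7.01,2.26,4.75,6380.35,***
psychological_distress,total,9.64,3.19,6.45,8663.85,***
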