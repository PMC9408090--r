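condition,measure,prevalence,adjusted_excess,cost_per_1000,stars
poor_sleep,absenteeism,64.4,1.41,1219708.39,
poor_sleep,presenteeism,64.4,2.17,1877139.86,*
poor_sleep,total,64.4,3.28,2837335.82,*
risky_alcohol,absenteeism,34.3,0.93,428477.58,
risky_alcohol,presenteeism,34.3,1.48,681878.29,
risky_alcohol,total,34.3,2.26,1041246.58,
smoking,absenteeism,26.4,-0.07,,
smoking,presenteeism,26.4,1.26,446812.69,
smoking,total,26.4,1.03,365251.65,
poor_diet,absenteeism,96.3,3.20,4139303.73,
poor_diet,presenteeism,96.3,4.26,5510448.09,*
poor_diet,total,96.3,6.85,8860697.05,*
weight_problem,absenteeism,74.5,1.00,1000707.84,
weight_problem,presenteeism,74.5,1.50,1501061.76,
weight_problem,total,74.5,2.21,2211564.33,
insufficient_pa,absenteeism,26.9,1.64,592580.23,
insufficient_pa,presenteeism,26.9,2.54,917776.70,**
insufficient_pa,total,26.9,3.88,1401958.10,**
poor_physical_health,absenteeism,8.8,2.79,329790.32,
poor_physical_health,presenteeism,8.8,9.05,1069749.96,***
poor_physical_health,total,8.8,11.10,1312069.02,***
psychological_distress,absenteeism,33.3,2.47,1104821.75,*
psychological_distress,presenteeism,33.3,4.64,2075454.63,***
psychological_distress,total,33.3,6.56,2934263.44,***
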