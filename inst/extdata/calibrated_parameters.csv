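parameter,description,scenario,mle,fit_mean,fit_sd,units
lambda_e_g,growth rate of endothelial (TIME) cells,1,3.7e-2,NA,NA,1/h
theta_e,carrying capacity of endothelial (TIME) cells,1,2.67e5,NA,NA,cells
lambda_T_g,growth rate of tumor (IBC3) cells,1,8.9e-3,NA,NA,1/h
lambda_T_p,VEGF production rate by tumor cells,2,1.7e-3,1.7e-3,2.3e-4,pg/(mL h cell)
lambda_e_c,VEGF consumption rate by endothelial cells,2,8.9e-7,9.1e-7,2.3e-7,1/(h cell)
theta_V,carrying capacity of VEGF,2,4035,4035,164.6,pg/mL
d_sc,stalk cell divide time,3,3.96,3.96,0.44,h
s_e,sprout elongation rate,derived,2.0,NA,NA,um/h
f_v,VEGF force coefficient,3,0.61,0.71,0.14,dimensionless
d_tip,distance between new tip cells,4,251,243.0,18.1,um
d_sc_local,local stalk cell divide time,5,10.86,10.85,2.4,h
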