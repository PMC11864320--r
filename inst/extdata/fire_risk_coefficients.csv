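term,symbol,role,estimate,std_error,p_value
Intercept,alpha,intercept,-0.17030,0.07410,0.022
PPT,beta1,beta,-0.00738,0.00070,0.000
TEMP,beta2,beta,0.07472,0.02325,0.001
ET,beta3,beta,-0.26480,0.07533,0.000
PPTs,beta4,beta,-0.00011,0.00013,0.401
TEMPs,beta5,beta,-0.08526,0.01618,0.000
ETs,beta6,beta,4.74e-7,4.07e-7,0.244
PPT^2,beta7,beta,0.00001,2.25e-6,0.000
TEMP^2,beta8,beta,-0.00556,0.00069,0.000
ET^2,beta9,beta,-0.05155,0.01604,0.001
PPTs^2,beta10,beta,-0.00304,0.00046,0.000
TEMPs^2,beta11,beta,2.47e-6,7.33e-7,0.001
ETs^2,beta12,beta,2.80e-12,9.47e-13,0.003
PPT*TEMP,beta13,beta,-0.00004,0.00005,0.413
PPT*ET,beta14,beta,0.00160,0.00031,0.000
PPT*PPTs,beta15,beta,-0.00001,2.02e-6,0.000
TEMP*TEMPs,beta16,beta,0.00644,0.00107,0.000
TEMP*ET,beta17,beta,0.02710,0.00363,0.000
ET*ETs,beta18,beta,-2.65e-7,8.39e-8,0.002
OWN,delta1,delta,0.01358,0.00292,0.000
rho,rho,rho,1.33100,0.00934,0.000
RMSE,rmse,stat,0.077,,
FI,fit_index,stat,0.56,,
n,n,stat,3854,,
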