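term,symbol,role,estimate,std_error,p_value
Intercept,alpha,intercept,2.26700,0.44450,0.000
PPT,beta1,beta,-0.00513,0.00213,0.016
TEMP,beta2,beta,0.10640,0.07137,0.136
ET,beta3,beta,-2.51700,0.60840,0.000
PPTs,beta4,beta,0.00038,0.00038,0.315
TEMPs,beta5,beta,-0.12660,0.05568,0.023
ETs,beta6,beta,1.00300,0.62190,0.107
PPT^2,beta7,beta,0.00001,0.00000,0.003
TEMP^2,beta8,beta,-0.00418,0.00214,0.050
ET^2,beta9,beta,0.54960,0.13870,0.000
PPTs^2,beta10,beta,3.85e-6,1.13e-6,0.001
TEMPs^2,beta11,beta,-0.00295,0.00163,0.070
ETs^2,beta12,beta,0.36410,0.15080,0.015
PPT*TEMP,beta13,beta,-0.00032,0.00009,0.001
PPT*ET,beta14,beta,0.00267,0.00077,0.001
PPT*PPTs,beta15,beta,-0.00002,4.00e-6,0.000
TEMP*TEMPs,beta16,beta,0.00778,0.00347,0.025
TEMP*ET,beta17,beta,0.00128,0.00806,0.874
ET*ETs,beta18,beta,-0.76150,0.26940,0.005
OWN,delta1,delta,0.05385,0.00843,0.000
AGE,delta2,delta,-0.00245,0.00007,0.000
AGBIO,delta3,delta,3.49e-7,9.74e-8,0.000
rho,rho,rho,0.42470,0.02871,0.000
RMSE,rmse,stat,0.237,,
FI,fit_index,stat,0.57,,
n,n,stat,4510,,
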