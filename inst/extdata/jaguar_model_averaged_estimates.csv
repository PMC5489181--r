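year,phi_male,phi_male_se,phi_female,phi_female_se,p_male,p_male_se,p_female,p_female_se,N_male,N_male_se,N_female,N_female_se,gamma,gamma_se
2002,0.79,0.05,0.79,0.06,0.36,0.02,0.07,0.02,11.31,0.57,NA,NA,0.21,0.04
2003,0.79,0.05,0.79,0.06,0.36,0.02,0.07,0.02,9.16,0.41,4.34,2.44,0.21,0.04
2004,0.78,0.05,0.78,0.05,0.36,0.02,0.07,0.02,14.16,0.41,12.09,4.30,0.21,0.04
2005,0.79,0.04,0.79,0.05,0.36,0.02,0.07,0.02,15.11,0.33,3.77,1.98,0.21,0.04
2006,0.79,0.04,0.78,0.05,0.36,0.02,0.07,0.02,16.29,0.55,2.17,1.66,0.21,0.04
2007,0.77,0.06,0.78,0.06,0.36,0.02,0.07,0.02,19.22,0.47,12.09,4.30,0.21,0.04
2008,0.79,0.04,0.79,0.04,0.36,0.02,0.07,0.02,11.20,0.45,6.51,3.09,0.21,0.04
2011,0.78,0.05,0.78,0.05,0.47,0.03,0.05,0.03,18.01,0.07,8.65,4.96,0.21,0.04
2012,0.77,0.06,0.78,0.06,0.27,0.03,0.06,0.03,17.14,0.39,7.91,2.96,0.21,0.04
2013,0.78,0.05,0.78,0.04,0.40,0.03,0.12,0.04,14.01,0.09,4.70,1.10,0.21,0.04
2014,0.78,0.05,0.78,0.05,0.33,0.04,0.16,0.04,12.06,0.26,7.81,1.10,0.21,0.04
2015,NA,NA,NA,NA,0.37,0.04,0.16,0.04,15.15,0.40,9.60,1.72,0.21,0.04
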