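analysis,factor_key,source,a,b,c,d,or_printed,ci_low_printed,ci_high_printed,p_printed,printed_or_consistent
lipophilicity,ro2,chen,71,101,10,163,11.50,5.42,24.82,<0.05,FALSE
lipophilicity,ro2,greene,51,123,6,59,4.08,1.57,11.23,<0.05,TRUE
lipophilicity,ro2,zhu,42,110,3,43,5.47,1.52,23.42,<0.05,TRUE
lipophilicity,ro2,sakatis,28,61,11,67,2.80,1.20,6.57,<0.05,TRUE
lipophilicity,ro2,xu,56,123,21,107,2.32,1.27,4.24,<0.05,TRUE
lipophilicity,ro2,consensus,99,214,23,232,4.77,2.79,7.86,<0.05,FALSE
lipophilicity,logp,chen,87,85,54,119,2.26,1.42,3.58,<0.05,TRUE
lipophilicity,logp,greene,69,105,18,47,1.72,0.88,3.36,0.098,TRUE
lipophilicity,logp,zhu,64,88,11,35,2.31,1.03,5.26,<0.05,TRUE
lipophilicity,logp,sakatis,35,54,30,48,1.03,0.53,2.03,1.0,FALSE
lipophilicity,logp,xu,74,105,54,74,0.97,0.59,1.57,0.91,TRUE
lipophilicity,logp,consensus,138,175,86,169,1.55,1.09,2.22,<0.05,TRUE
lipophilicity,dose,chen,139,33,70,103,6.20,3.71,10.39,<0.05,TRUE
lipophilicity,dose,greene,123,51,31,34,2.65,1.41,4.96,<0.05,TRUE
lipophilicity,dose,zhu,110,42,22,24,2.86,1.37,5.96,<0.05,TRUE
lipophilicity,dose,sakatis,73,16,30,48,7.30,3.41,15.83,<0.05,TRUE
lipophilicity,dose,xu,127,52,63,65,2.52,1.52,4.16,<0.05,TRUE
lipophilicity,dose,consensus,225,88,107,148,3.54,2.46,5.10,<0.05,TRUE
metabolism,metabolism-dose,chen,76,31,19,86,11.09,5.54,22.48,<0.05,FALSE
metabolism,metabolism-dose,greene,81,58,11,34,4.32,1.91,9.92,<0.05,TRUE
metabolism,metabolism-dose,zhu,70,57,6,26,5.32,1.90,15.57,<0.05,TRUE
metabolism,metabolism-dose,sakatis,53,20,17,48,7.48,3.30,17.20,<0.05,TRUE
metabolism,metabolism-dose,xu,84,57,28,72,3.79,2.11,6.84,<0.05,TRUE
metabolism,metabolism-dose,consensus,127,94,35,142,5.48,3.40,8.84,<0.05,TRUE
metabolism,metabolism,chen,91,16,72,33,2.67,1.27,5.40,<0.05,FALSE
metabolism,metabolism,greene,109,30,27,18,2.42,1.11,5.29,<0.05,TRUE
metabolism,metabolism,zhu,98,29,21,11,1.77,0.70,4.42,0.18,TRUE
metabolism,metabolism,sakatis,61,12,48,17,1.80,0.73,4.48,0.21,TRUE
metabolism,metabolism,xu,112,29,67,33,1.92,1.02,3.56,<0.05,FALSE
metabolism,metabolism,consensus,174,47,117,60,1.90,1.18,3.05,<0.05,TRUE
metabolism,dose,chen,87,20,38,67,7.67,3.92,15.15,<0.05,TRUE
metabolism,dose,greene,99,40,23,22,2.37,1.12,5.00,<0.05,TRUE
metabolism,dose,zhu,90,37,14,18,3.13,1.32,7.49,<0.05,TRUE
metabolism,dose,sakatis,61,12,26,39,7.63,3.23,18.33,<0.05,TRUE
metabolism,dose,xu,101,40,51,49,2.43,1.37,4.30,<0.05,TRUE
metabolism,dose,consensus,160,61,70,107,4.01,2.57,6.26,<0.05,TRUE
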