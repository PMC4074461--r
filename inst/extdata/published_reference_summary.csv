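comparison,task,metric,mean_a,sd_a,mean_b,sd_b,diff_mean,diff_sd,icc,ci_low,ci_high,sem_reported
inter_rater,STOE,PL,36.03,7.88,33.92,6.23,-2.11,3.90,0.918,0.794,0.968,1.955
inter_rater,STOE,VA,1.27,0.28,1.19,0.22,-0.08,0.14,0.918,0.794,0.968,0.069
inter_rater,STCE,PL,39.79,6.37,37.86,7.68,-1.92,3.79,0.922,0.804,0.969,1.899
inter_rater,STCE,VA,1.40,0.22,1.34,0.27,-0.06,0.14,0.915,0.785,0.966,0.070
inter_rater,SOOE,PL,44.42,8.54,42.17,8.57,-2.25,8.18,0.704,0.252,0.883,4.090
inter_rater,SOOE,VA,4.71,0.94,4.43,0.89,-0.27,0.90,0.685,0.205,0.875,0.450
inter_rater,SOCE,PL,81.03,18.02,85.95,22.70,4.92,14.25,0.862,0.653,0.946,7.138
inter_rater,SOCE,VA,8.58,1.88,9.10,2.41,0.52,1.47,0.869,0.670,0.948,0.735
intra_rater,STOE,PL,36.03,7.88,36.34,5.24,0.31,4.50,0.872,0.678,0.950,2.254
intra_rater,STOE,VA,1.27,0.28,1.28,0.19,0.01,0.16,0.864,0.657,0.946,0.082
intra_rater,STCE,PL,39.79,6.37,39.56,6.54,-0.23,4.08,0.889,0.720,0.956,2.041
intra_rater,STCE,VA,1.40,0.22,1.39,0.23,0.01,0.14,0.891,0.724,0.957,0.071
intra_rater,SOOE,PL,44.42,8.54,44.76,10.97,0.34,8.22,0.788,0.465,0.916,4.112
intra_rater,SOOE,VA,4.71,0.94,4.73,1.17,0.03,0.90,0.785,0.457,0.915,0.448
intra_rater,SOCE,PL,81.03,18.02,85.47,18.65,4.44,15.20,0.793,0.476,0.918,7.593
intra_rater,SOCE,VA,8.58,1.88,9.04,1.95,0.46,1.61,0.786,0.458,0.915,0.803
validity,STOE,PL,36.03,7.88,35.03,8.82,-1.00,5.64,0.872,0.676,0.949,5.941
validity,STOE,VA,1.27,0.28,1.17,0.29,-0.10,0.19,0.870,0.672,0.949,0.622
validity,STCE,PL,39.79,6.37,36.67,4.99,-3.11,4.36,0.831,0.572,0.933,2.175
validity,STCE,VA,1.40,0.22,1.22,0.17,-0.18,0.15,0.824,0.556,0.931,0.076
validity,SOOE,PL,44.42,8.54,41.34,8.54,-3.09,6.78,0.813,0.528,0.926,3.390
validity,SOOE,VA,4.71,0.94,4.14,0.85,-0.57,0.70,0.820,0.544,0.929,0.352
validity,SOCE,PL,81.03,18.02,70.36,17.81,-10.67,13.44,0.836,0.586,0.935,3.188
validity,SOCE,VA,8.58,1.88,6.80,2.01,-1.78,1.79,0.731,0.321,0.894,0.140
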