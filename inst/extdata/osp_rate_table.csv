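depth_m,start_date,treatment,days_to_stationary,days_to_final,doc0,doc0_sd,doc_final,doc_final_sd,short_rate,short_rate_sd,short_n,short_p,long_rate,long_n,long_p,bp_gundersen,bp_gundersen_sd,bp_exports,bp_exports_sd,bp_malfatti,bp_malfatti_sd,bge_gundersen,bge_gundersen_sd,bge_exports,bge_exports_sd,bge_malfatti,bge_malfatti_sd
5,Aug-15,diluted,6,93,57.7,0.4,56.6,0.5,0.06,0.04,4,0.21,NA,NA,NA,0.09,0.02,0.12,0.02,0.16,0.03,NA,NA,NA,NA,NA,NA
5,Aug-15,undiluted,6,93,60.4,0.8,56.3,0.2,0.14,0.12,4,0.15,0.015,5,0.007,0.14,0.01,0.19,0.01,0.27,0.02,NA,NA,NA,NA,NA,NA
5,Aug-18,diluted,6,90,57.7,0.4,56.0,0.5,0.05,0.07,3,0.54,0.014,5,0.03,0.05,0.01,0.08,0.02,0.12,0.03,NA,NA,NA,NA,NA,NA
5,Aug-18,undiluted,6,90,60.0,0.3,53.9,0.4,0.38,0.01,3,0.0005,0.046,4,0.04,0.07,0.01,0.10,0.01,0.15,0.01,0.18,0.02,0.27,0.03,0.39,0.04
5,Aug-23,diluted,10,85,57.8,0.4,57.0,0.5,0.08,0.06,3,0.22,NA,NA,NA,0.05,0.01,0.07,0.01,0.10,0.01,NA,NA,NA,NA,NA,NA
5,Aug-23,undiluted,10,85,59.6,0.4,57.1,0.7,0.11,0.02,4,0.005,0.021,6,0.009,0.03,0.01,0.05,0.01,0.07,0.01,0.27,0.09,0.45,0.13,0.68,0.18
5,Aug-28,diluted,9,80,59.6,0.5,56.8,0.4,0.18,0.03,3,0.003,0.016,6,0.03,0.03,0.01,0.07,0.01,0.11,0.01,0.26,0.06,0.38,0.09,0.55,0.13
5,Aug-28,undiluted,9,80,61.2,0.4,56.8,0.9,0.22,0.06,3,0.008,0.031,6,0.01,0.04,0.00,0.07,0.01,0.11,0.01,0.19,0.05,0.32,0.09,0.48,0.13
5,Aug-31,diluted,10,77,59.8,0.6,55.0,0.4,0.19,0.05,4,0.003,0.044,6,0.0005,0.03,0.01,0.05,0.01,0.07,0.02,0.18,0.07,0.27,0.10,0.39,0.14
5,Aug-31,undiluted,10,77,59.3,0.4,54.3,0.2,0.24,0.06,4,0.003,0.039,6,0.01,0.04,0.01,0.07,0.01,0.10,0.01,0.14,0.05,0.27,0.07,0.42,0.11
35,Aug-23,diluted,10,85,58.0,0.5,56.5,0.6,0.09,0.06,3,0.19,0.018,4,0.02,0.05,0.01,0.06,0.01,0.09,0.01,NA,NA,NA,NA,NA,NA
35,Aug-23,undiluted,10,85,58.7,0.5,55.9,0.9,0.03,0.02,3,0.29,0.017,5,0.08,0.02,0.00,0.03,0.00,0.05,0.00,NA,NA,NA,NA,NA,NA
50,Aug-15,diluted,10,93,57.3,0.4,56.3,0.6,0.10,0.02,5,0.003,0.014,5,0.18,0.03,0.00,0.04,0.01,0.05,0.01,0.25,0.06,0.35,0.10,0.47,0.12
50,Aug-15,undiluted,10,93,56.9,0.5,54.7,0.3,0.16,0.03,5,0.003,0.021,6,0.05,0.02,0.01,0.04,0.01,0.06,0.01,0.13,0.05,0.25,0.07,0.41,0.11
50,Aug-28,diluted,9,80,56.9,0.4,54.0,0.7,0.12,0.09,3,0.25,0.023,6,0.0005,0.01,0.00,0.01,0.01,0.01,0.01,NA,NA,NA,NA,NA,NA
50,Aug-28,undiluted,9,80,58.6,0.4,56.9,0.3,0.20,0.03,3,0.0005,0.010,6,0.29,0.02,0.00,0.02,0.00,0.03,0.00,0.25,0.05,0.33,0.06,0.46,0.08
95,Aug-15,diluted,10,93,54.5,0.3,54.3,0.5,0.04,0.03,5,0.49,NA,NA,NA,0.01,0.00,0.01,0.01,0.01,0.01,NA,NA,NA,NA,NA,NA
95,Aug-15,undiluted,10,93,54.2,0.6,52.4,0.6,0.13,0.05,5,0.03,0.007,5,0.005,0.03,0.00,0.04,0.00,0.05,0.00,0.13,0.05,0.19,0.08,0.27,0.11
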