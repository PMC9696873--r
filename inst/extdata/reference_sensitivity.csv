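variable,rule,sem_all,sem_pct_all,swc_all,md_all,md_pct_all,sem_s1s2,sem_pct_s1s2,swc_s1s2,md_s1s2,md_pct_s1s2,sem_s1s3,sem_pct_s1s3,swc_s1s3,md_s1s3,md_pct_s1s3,sem_s2s3,sem_pct_s2s3,swc_s2s3,md_s2s3,md_pct_s2s3
peak_torque,avg,9.6,3.8,17.7,26.7,10.6,9.8,3.8,18.2,27.0,10.6,13.4,5.4,17.4,37.2,14.8,12.2,4.9,17.9,33.7,13.6
peak_torque,highest,15.6,6,18.3,43.1,16.7,14.5,5.6,18.5,40.3,15.5,17.0,6.6,18.0,47.0,18.2,15.8,6.2,18.7,43.8,17.1
grip_force,avg,1.2,2.7,2.4,3.4,7.4,0.8,1.7,2.3,2.2,4.8,1.8,3.9,2.5,5.0,10.8,1.7,3.7,2.5,4.8,10.4
grip_force,highest,1.8,3.8,2.5,5.1,10.7,1.1,2.4,2.4,3.1,6.6,2.0,4.3,2.6,5.7,11.8,2.2,4.7,2.5,6.2,12.9
jump_height,avg,0.8,1.8,2.0,2.2,5.1,1.0,2.3,2.1,2.9,6.5,1.1,2.5,2.1,3.0,6.8,1.0,2.2,2.0,2.7,6.1
jump_height,highest,1.7,2.7,2.1,4.7,10.3,1.5,3.2,2.1,4.1,8.9,1.9,4.2,2.1,5.3,11.5,1.8,4,2.1,5.1,11
peak_power,avg,0.8,1.7,1.9,2.1,4.5,0.9,2,2.0,2.6,5.6,0.9,2,1.9,2.6,5.5,1.0,2.2,1.9,2.9,6.2
peak_power,highest,1.9,3.9,2.0,5.2,10.8,2.0,4.1,2.0,5.4,11.4,1.6,3.3,2.0,4.3,9.1,2.0,4.3,1.9,5.7,11.9
hop_peak_force,avg,0.16,4.5,0.20,0.45,12.5,0.17,4.8,0.20,0.47,13.4,0.23,6.4,0.21,0.65,17.8,0.19,5.1,0.20,0.53,14.3
hop_peak_force,highest,0.25,6.7,0.21,0.70,18.4,0.26,6.9,0.21,0.71,19.2,0.30,7.7,0.22,0.82,21.4,0.21,5.6,0.20,0.59,15.4
hop_contact_time,avg,0.015,8.6,0.004,0.042,23.8,0.012,6.9,0.004,0.034,19.1,0.019,10.8,0.005,0.054,29.9,0.019,10.7,0.004,0.052,29.8
hop_contact_time,lowest,0.012,7.0,0.003,0.032,19.3,0.009,5.6,0.003,0.026,15.6,0.012,7,0.003,0.033,19.4,0.013,8.1,0.004,0.037,22.4
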