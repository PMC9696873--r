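variable,rule,mean_s1,sd_s1,mean_s2,sd_s2,mean_s3,sd_s3,icc_all,ci_lo_all,ci_hi_all,cv_all,icc_s1s2,ci_lo_s1s2,ci_hi_s1s2,cv_s1s2,icc_s1s3,ci_lo_s1s3,ci_hi_s1s3,cv_s1s3,icc_s2s3,ci_lo_s2s3,ci_hi_s2s3,cv_s2s3
peak_torque,avg,256.2,90,252.9,95,244.6,87,0.988,0.973,0.995,6.2,0.988,0.970,0.996,5.1,0.976,0.929,0.992,6.7,0.981,0.949,0.993,5.3
peak_torque,highest,262.2,90,258.8,98,253.6,92,0.971,0.937,0.989,6.1,0.975,0.937,0.991,4.9,0.964,0.904,0.987,6.3,0.972,0.925,0.990,5.4
grip_force,avg,45.5,12,45.9,12,46.5,13,0.990,0.977,0.996,3.9,0.995,0.987,0.998,2.2,0.979,0.942,0.992,3.7,0.980,0.947,0.993,4.4
grip_force,highest,47.7,12,47.9,12,48.4,14,0.978,0.952,0.991,3.4,0.991,0.977,0.997,2.2,0.975,0.933,0.991,3.1,0.969,0.917,0.988,3.9
jump_height,avg,44.2,11,44.0,10,44.7,10,0.994,0.986,0.998,3.1,0.990,0.974,0.996,2.6,0.989,0.970,0.996,3.0,0.991,0.974,0.997,2.6
jump_height,highest,45.6,11,45.9,10,46.3,11,0.973,0.942,0.989,3.3,0.980,0.947,0.992,2.4,0.968,0.917,0.988,3.3,0.968,0.916,0.988,3.2
peak_power,avg,46.7,10,45.9,10,46.7,10,0.994,0.986,0.997,2.8,0.991,0.969,0.997,2.2,0.991,0.975,0.997,2.6,0.988,0.966,0.996,2.7
peak_power,highest,48.0,11,47.4,10,47.8,10,0.965,0.923,0.986,3.2,0.962,0.904,0.986,2.8,0.976,0.935,0.991,2.6,0.955,0.882,0.984,3.2
hop_peak_force,avg,3.48,1,3.58,1,3.81,1,0.975,0.925,0.991,7.1,0.972,0.926,0.989,5.7,0.949,0.629,0.986,7.8,0.965,0.830,0.989,5.6
hop_peak_force,highest,3.69,1,3.74,1,3.95,1,0.942,0.859,0.978,6.4,0.94,0.848,0.977,5.6,0.926,0.703,0.976,6.7,0.956,0.748,0.987,4.9
hop_contact_time,avg,0.182,0.02,0.171,0.02,0.180,0.02,0.526,-0.031,0.811,8.5,0.659,0.090,0.872,6.0,0.32,-1.014,0.760,8.9,0.256,-0.909,0.723,7.9
hop_contact_time,lowest,0.168,0.02,0.165,0.02,0.169,0.02,0.536,0.250,0.776,6.2,0.667,0.316,0.859,4.5,0.511,0.039,0.792,5.7,0.457,-0.006,0.761,6.4
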