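patient_id,lesion_id,session,tumor_volume_cm3,k1,suv_max,suv_mean,suv_peak,voi_source
1,1,test,3.92,0.36,5.00,2.99,3.88,psma_suv6
1,1,retest,3.92,0.34,5.14,3.20,3.84,psma_suv6
2,1,test,21.30,0.27,4.10,2.55,3.58,psma_suv6
2,1,retest,21.30,0.25,5.42,3.10,4.18,psma_suv6
3,1,test,0.46,0.05,1.44,1.12,1.22,mri_manual
3,1,retest,0.46,0.05,1.50,1.15,1.11,mri_manual
4,1,test,2.21,0.12,3.77,2.52,2.77,psma_suv6
4,1,retest,2.21,0.10,5.27,3.38,3.31,psma_suv6
5,1,test,13.49,0.22,5.50,2.46,4.45,psma_suv6
5,1,retest,13.49,0.16,6.26,3.09,5.15,psma_suv6
6,1,test,36.83,0.23,6.04,3.61,4.96,psma_suv6
6,1,retest,36.83,0.29,4.85,2.93,3.86,psma_suv6
7,1,test,0.88,0.23,4.97,3.73,3.77,psma_suv6
7,1,retest,0.88,0.26,4.85,4.02,4.09,psma_suv6
8,1,test,0.84,0.08,3.15,1.57,2.16,mri_manual
8,1,retest,0.84,0.09,2.25,1.05,1.33,mri_manual
8,2,test,0.91,0.13,2.62,1.57,2.36,mri_manual
8,2,retest,0.91,0.12,2.07,1.18,1.48,mri_manual
9,1,test,1.47,0.05,1.63,0.93,1.16,mri_manual
9,1,retest,1.47,0.05,1.67,1.11,1.38,mri_manual
10,1,test,18.99,0.43,5.99,3.02,5.05,psma_suv6
10,1,retest,18.99,0.40,4.06,2.19,3.32,psma_suv6
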