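score_id,disease,metric_kind,value,extreme_fraction,source,notes
GPS_2018,coronary artery disease,or_per_sd,1.49,,"Khera et al. 2018, reported OR per SD","2018 genome-wide score"
GPS_Mult_2023,coronary artery disease,or_per_sd,1.73,,"Patel et al. 2023, reported OR per SD","2023 multi-ancestry score"
BC_PRS_EUR,breast cancer,dr5,0.15,,"published European-ancestry screening performance","detection rate at 5% FPR"
BC_PRS_313,breast cancer,auc,0.64,,"Mavaddat et al. 2019, reported AUC","313-SNP score"
T2D_QUINTILE,type 2 diabetes,extreme_quantile_or,3.4,0.20,"reported top vs bottom quintile OR","quintile comparison"
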