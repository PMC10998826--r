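# Summary statistics exactly as printed in the published stability and
# dosimetry tables (medians, IQRs, exact Wilcoxon p-values). Used by the
# report layer to flag agreement of recomputed statistics with print.
# Several printed cells do not reproduce from the printed per-patient
# values under standard conventions (see package vignette); they are kept
# verbatim here and compared, never forced. The 60-min "with" median/IQR
# pair is typeset run-on ("64.1510") and transcribed as 64.15 / 10.
table,endpoint,arm,time_min,statistic,printed
stability,stability,without,5,median,94.1
stability,stability,without,5,iqr,2.7
stability,stability,with,5,median,99.5
stability,stability,with,5,iqr,1.5
stability,stability,without,15,median,80.3
stability,stability,without,15,iqr,19.3
stability,stability,with,15,median,92.1
stability,stability,with,15,iqr,2.7
stability,stability,without,30,median,64.5
stability,stability,without,30,iqr,9.8
stability,stability,with,30,median,78.5
stability,stability,with,30,iqr,4.9
stability,stability,without,60,median,41.1
stability,stability,without,60,iqr,11.2
stability,stability,with,60,median,64.15
stability,stability,with,60,iqr,10
dose,tumor_dose,without,NA,median,0.28
dose,tumor_dose,with,NA,median,0.74
dose,tumor_dose,without,NA,iqr,0.34
dose,tumor_dose,with,NA,iqr,0.79
dose,kidney_dose,without,NA,median,0.05
dose,kidney_dose,with,NA,median,0.11
dose,kidney_dose,without,NA,iqr,0.01
dose,kidney_dose,with,NA,iqr,0.04
dose,stomach_dose,without,NA,median,0.2
dose,stomach_dose,with,NA,median,0.5
dose,stomach_dose,without,NA,iqr,0.05
dose,stomach_dose,with,NA,iqr,0.37
dose,marrow_dose,without,NA,median,0.03
dose,marrow_dose,with,NA,median,0.05
dose,marrow_dose,without,NA,iqr,0.002
dose,marrow_dose,with,NA,iqr,0.014
dose,ratio_kidney,without,NA,median,8.3
dose,ratio_kidney,with,NA,median,7.8
dose,ratio_kidney,without,NA,iqr,9.5
dose,ratio_kidney,with,NA,iqr,8.1
dose,ratio_stomach,without,NA,median,1.5
dose,ratio_stomach,with,NA,median,1.1
dose,ratio_stomach,without,NA,iqr,2.1
dose,ratio_stomach,with,NA,iqr,1.5
dose,ratio_marrow,without,NA,median,9.2
dose,ratio_marrow,with,NA,median,19.1
dose,ratio_marrow,without,NA,iqr,11.4
dose,ratio_marrow,with,NA,iqr,15.7
dose,tumor_dose,NA,NA,p_wilcoxon,0.03
dose,kidney_dose,NA,NA,p_wilcoxon,0.01
dose,stomach_dose,NA,NA,p_wilcoxon,0.01
dose,marrow_dose,NA,NA,p_wilcoxon,0.01
dose,ratio_kidney,NA,NA,p_wilcoxon,0.22
dose,ratio_stomach,NA,NA,p_wilcoxon,0.19
dose,ratio_marrow,NA,NA,p_wilcoxon,0.44
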