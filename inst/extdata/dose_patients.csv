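# Per-patient/per-lesion radiation dosimetry of a Lu-177 minigastrin
# radioligand without and with sacubitril/valsartan premedication,
# transcribed from the published per-patient table. Units: Gy/GBq for
# *_dose endpoints, dimensionless for ratio_* endpoints. Tumor endpoints
# exist for 6 lesions in 4 patients (lesion 2 = second tumor in the same
# patient); organ doses are per patient (lesion NA) and were printed
# repeated on second-lesion rows - they are packaged once per patient.
# Patients 1-3 and 5 had no measurable tumor (n.a. in print; omitted here).
patient,lesion,arm,endpoint,value
4,1,without,tumor_dose,0.03
4,1,with,tumor_dose,0.05
4,2,without,tumor_dose,0.05
4,2,with,tumor_dose,0.07
6,1,without,tumor_dose,0.99
6,1,with,tumor_dose,1.26
7,1,without,tumor_dose,0.22
7,1,with,tumor_dose,0.75
7,2,without,tumor_dose,0.47
7,2,with,tumor_dose,1.12
8,1,without,tumor_dose,0.33
8,1,with,tumor_dose,0.73
1,NA,without,kidney_dose,0.04
1,NA,with,kidney_dose,0.07
2,NA,without,kidney_dose,0.05
2,NA,with,kidney_dose,0.13
3,NA,without,kidney_dose,0.05
3,NA,with,kidney_dose,0.12
4,NA,without,kidney_dose,0.05
4,NA,with,kidney_dose,0.12
5,NA,without,kidney_dose,0.03
5,NA,with,kidney_dose,0.07
6,NA,without,kidney_dose,0.05
6,NA,with,kidney_dose,0.11
7,NA,without,kidney_dose,0.04
7,NA,with,kidney_dose,0.10
8,NA,without,kidney_dose,0.03
8,NA,with,kidney_dose,0.09
1,NA,without,stomach_dose,0.30
1,NA,with,stomach_dose,0.48
2,NA,without,stomach_dose,0.26
2,NA,with,stomach_dose,0.43
3,NA,without,stomach_dose,0.03
3,NA,with,stomach_dose,0.05
4,NA,without,stomach_dose,0.23
4,NA,with,stomach_dose,0.50
5,NA,without,stomach_dose,1.15
5,NA,with,stomach_dose,1.53
6,NA,without,stomach_dose,0.19
6,NA,with,stomach_dose,0.30
7,NA,without,stomach_dose,0.17
7,NA,with,stomach_dose,0.88
8,NA,without,stomach_dose,0.20
8,NA,with,stomach_dose,0.39
1,NA,without,marrow_dose,0.02
1,NA,with,marrow_dose,0.02
2,NA,without,marrow_dose,0.04
2,NA,with,marrow_dose,0.04
3,NA,without,marrow_dose,0.03
3,NA,with,marrow_dose,0.04
4,NA,without,marrow_dose,0.03
4,NA,with,marrow_dose,0.05
5,NA,without,marrow_dose,0.02
5,NA,with,marrow_dose,0.03
6,NA,without,marrow_dose,0.04
6,NA,with,marrow_dose,0.06
7,NA,without,marrow_dose,0.03
7,NA,with,marrow_dose,0.04
8,NA,without,marrow_dose,0.03
8,NA,with,marrow_dose,0.04
4,1,without,ratio_kidney,0.6
4,1,with,ratio_kidney,0.4
4,2,without,ratio_kidney,1.0
4,2,with,ratio_kidney,0.6
6,1,without,ratio_kidney,19.8
6,1,with,ratio_kidney,11.5
7,1,without,ratio_kidney,5.5
7,1,with,ratio_kidney,7.5
7,2,without,ratio_kidney,11.8
7,2,with,ratio_kidney,11.2
8,1,without,ratio_kidney,11.0
8,1,with,ratio_kidney,8.1
4,1,without,ratio_stomach,0.1
4,1,with,ratio_stomach,0.1
4,2,without,ratio_stomach,0.2
4,2,with,ratio_stomach,0.1
6,1,without,ratio_stomach,5.2
6,1,with,ratio_stomach,4.2
7,1,without,ratio_stomach,1.3
7,1,with,ratio_stomach,0.9
7,2,without,ratio_stomach,2.8
7,2,with,ratio_stomach,1.3
8,1,without,ratio_stomach,1.7
8,1,with,ratio_stomach,1.9
4,1,without,ratio_marrow,1.1
4,1,with,ratio_marrow,1.0
4,2,without,ratio_marrow,1.8
4,2,with,ratio_marrow,1.4
6,1,without,ratio_marrow,24.8
6,1,with,ratio_marrow,21.4
7,1,without,ratio_marrow,7.3
7,1,with,ratio_marrow,20.3
7,2,without,ratio_marrow,15.7
7,2,with,ratio_marrow,30.3
8,1,without,ratio_marrow,11.0
8,1,with,ratio_marrow,17.8
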