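# Per-patient in-vivo stability (% intact peptide of initial signal) of a
# Lu-177 minigastrin radioligand at 5/15/30/60 min p.i., without ("without")
# and with ("with") a single oral sacubitril/valsartan premedication, in a
# randomized cross-over study of 8 patients. Transcribed from the published
# per-patient table. evaluable=FALSE rows carry the footnoted reason.
# Transcription note: the published table is typeset as run-on digits; the
# 5-min patient-1 "71" cell and the 60-min "with" median/IQR cells are
# ambiguous on parsing and are transcribed as parsed, not corrected.
patient,arm,time_min,percent_intact,evaluable,note
1,without,5,71,TRUE,
2,without,5,95.5,TRUE,
3,without,5,NA,FALSE,activity too low for HPLC analysis
4,without,5,96.1,TRUE,
5,without,5,94.3,TRUE,
6,without,5,96.5,TRUE,
7,without,5,93.9,TRUE,
8,without,5,92.4,TRUE,
1,with,5,91.4,TRUE,
2,with,5,99.4,TRUE,
3,with,5,98.3,TRUE,
4,with,5,NA,FALSE,HPLC malfunction
5,with,5,99.6,TRUE,
6,with,5,99.9,TRUE,
7,with,5,100,TRUE,
8,with,5,98.3,TRUE,
1,without,15,69.9,TRUE,
2,without,15,80.3,TRUE,
3,without,15,91.4,TRUE,
4,without,15,90.5,TRUE,
5,without,15,88.8,TRUE,
6,without,15,90.2,TRUE,
7,without,15,71.4,TRUE,
8,without,15,68.1,TRUE,
1,with,15,92.2,TRUE,
2,with,15,96.7,TRUE,
3,with,15,92.1,TRUE,
4,with,15,NA,FALSE,HPLC malfunction
5,with,15,91.6,TRUE,
6,with,15,99.2,TRUE,
7,with,15,92,TRUE,
8,with,15,88.9,TRUE,
1,without,30,64.5,TRUE,
2,without,30,72.3,TRUE,
3,without,30,74.8,TRUE,
4,without,30,67.6,TRUE,
5,without,30,NA,FALSE,activity too low for HPLC analysis
6,without,30,60.3,TRUE,
7,without,30,50.1,TRUE,
8,without,30,NA,FALSE,activity too low for HPLC analysis
1,with,30,78.5,TRUE,
2,with,30,85.7,TRUE,
3,with,30,80.6,TRUE,
4,with,30,NA,FALSE,HPLC malfunction
5,with,30,85.5,TRUE,
6,with,30,77.9,TRUE,
7,with,30,75.3,TRUE,
8,with,30,79.9,TRUE,
1,without,60,37.9,TRUE,
2,without,60,47.1,TRUE,
3,without,60,44.3,TRUE,
4,without,60,34.3,TRUE,
5,without,60,NA,FALSE,activity too low for HPLC analysis
6,without,60,53.7,TRUE,
7,without,60,26,TRUE,
8,without,60,NA,FALSE,activity too low for HPLC analysis
1,with,60,63.5,TRUE,
2,with,60,70.3,TRUE,
3,with,60,64.8,TRUE,
4,with,60,NA,FALSE,HPLC malfunction
5,with,60,75.6,TRUE,
6,with,60,NA,FALSE,HPLC malfunction
7,with,60,54.8,TRUE,
8,with,60,58.8,TRUE,
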